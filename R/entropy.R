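#' Entropy-analysis parameters
#'
#' Defaults follow the standard regularity-statistic settings for
#' short physiological series: embedding dimension `m = 2` and tolerance
#' `r = 0.25 x SD` for approximate and sample entropy (requiring at least
#' 200 points), and 3-decimal amplitude discretisation with at least 50
#' samples for Shannon entropy.
#'
#' @param m Embedding dimension (>= 1).
#' @param r_frac Tolerance as a fraction of the signal SD (> 0).
#' @param shannon_precision Decimal places for amplitude discretisation.
#' @param min_len_shannon Minimum sample count for Shannon entropy.
#' @param min_len_apen_sampen Minimum sample count for ApEn/SampEn.
#' @param decimate_to_hz Target rate for optional decimation before
#'   ApEn/SampEn (`NULL` to disable). Bandpassed EMG carries no content
#'   above the 1000 Hz corner, so decimating 20 kHz recordings to 2 kHz
#'   is alias-safe and keeps the quadratic template search tractable.
#' @return An object of class `entropy_params`.
#' @export
entropy_params <- function(m = 2, r_frac = 0.25, shannon_precision = 3,
                           min_len_shannon = 50, min_len_apen_sampen = 200,
                           decimate_to_hz = 2000) {
  if (m < 1) stop("m must be >= 1")
  if (r_frac <= 0) stop("r_frac must be > 0")
  if (shannon_precision < 0) stop("shannon_precision must be >= 0")
  structure(list(m = as.integer(m), r_frac = r_frac,
                 shannon_precision = as.integer(shannon_precision),
                 min_len_shannon = min_len_shannon,
                 min_len_apen_sampen = min_len_apen_sampen,
                 decimate_to_hz = decimate_to_hz),
            class = "entropy_params")
}

#' Clean a signal for entropy analysis
#'
#' Removes non-finite samples and subtracts the least-squares linear
#' trend (artifact and baseline-drift handling ahead of the stationarity
#' assumption of the template-matching entropies).
#'
#' @param x A [sampled_signal] or numeric vector.
#' @return Same type as the input, cleaned.
#' @export
clean_for_entropy <- function(x) {
  is_sig <- inherits(x, "sampled_signal")
  v <- if (is_sig) x$samples else as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("all samples non-finite")
  if (length(v) > 1 && diff(range(v)) > 0) {
    i <- seq_along(v)
    v <- stats::lsfit(i, v)$residuals
  } else v <- v - v   # constant input: exactly zero residual
  if (is_sig) sampled_signal(v, x$rate, x$label, x$units, t0 = x$t0) else v
}

#' Shannon entropy of the amplitude distribution
#'
#' Amplitudes are discretised to `shannon_precision` decimal places; the
#' entropy of the empirical distribution of the discretised values is
#' returned in bits. Signals shorter than `min_len_shannon` finite
#' samples are flagged invalid rather than raising an error, so batch
#' tables stay rectangular.
#'
#' @param x A [sampled_signal] or numeric vector (cleaned or raw; only
#'   finite values are used).
#' @param params An [entropy_params()].
#' @return Numeric value in bits, with attribute `valid` (logical).
#' @export
shannon_entropy <- function(x, params = entropy_params()) {
  v <- if (inherits(x, "sampled_signal")) x$samples else as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) < params$min_len_shannon)
    return(structure(NA_real_, valid = FALSE, reason = "too few samples"))
  disc <- round(v, params$shannon_precision)
  p <- tabulate(factor(disc)) / length(disc)
  structure(-sum(p * log2(p)), valid = TRUE)
}

# shared preparation for the template entropies: clean, optionally
# decimate, gate on length and SD
prepare_template_signal <- function(x, params) {
  rate <- if (inherits(x, "sampled_signal")) x$rate else NULL
  v <- clean_for_entropy(if (inherits(x, "sampled_signal")) x$samples else x)
  if (!is.null(rate) && !is.null(params$decimate_to_hz) &&
      rate > params$decimate_to_hz) {
    step <- max(1L, floor(rate / params$decimate_to_hz))
    v <- v[seq(1L, length(v), by = step)]
  }
  v
}

#' Approximate entropy (ApEn)
#'
#' Standard ApEn: `Phi(m) - Phi(m+1)` with Chebyshev distance,
#' self-matches included and counts normalised per template. Tolerance is
#' `r_frac` times the sample standard deviation of the cleaned signal.
#'
#' @inheritParams shannon_entropy
#' @return Numeric value in nats with attributes `valid`, `degenerate`
#'   (constant input), `n` (samples used) and `r`.
#' @export
approximate_entropy <- function(x, params = entropy_params()) {
  v <- prepare_template_signal(x, params)
  n <- length(v)
  if (n < params$min_len_apen_sampen)
    return(structure(NA_real_, valid = FALSE, n = n, reason = "too few samples"))
  s <- stats::sd(v)
  if (s == 0)
    return(structure(0, valid = TRUE, degenerate = TRUE, n = n, r = 0))
  r <- params$r_frac * s
  structure(.apen_core(v, params$m, r),
            valid = TRUE, degenerate = FALSE, n = n, r = r)
}

#' Sample entropy (SampEn)
#'
#' `SampEn(m, r, N) = -ln(A / B)`, where `B` counts ordered pairs of
#' distinct length-`m` templates within Chebyshev tolerance `r` and `A`
#' the same for length-`m+1` templates; self-matches are excluded.
#' Tolerance is `r_frac` times the sample standard deviation of the
#' cleaned signal. When no template pair matches (`A = 0` or `B = 0`) the
#' measure is flagged invalid instead of returning an infinity.
#'
#' @inheritParams shannon_entropy
#' @return Numeric value in nats with attributes `valid`, `degenerate`,
#'   `n`, `r`, and the match counts `A` and `B` (ordered pairs).
#' @export
sample_entropy <- function(x, params = entropy_params()) {
  v <- prepare_template_signal(x, params)
  n <- length(v)
  if (n < params$min_len_apen_sampen)
    return(structure(NA_real_, valid = FALSE, n = n, reason = "too few samples"))
  s <- stats::sd(v)
  if (s == 0)
    return(structure(0, valid = TRUE, degenerate = TRUE, n = n, r = 0,
                     A = NA_real_, B = NA_real_))
  r <- params$r_frac * s
  cnt <- .sampen_counts(v, params$m, r)
  A <- 2 * cnt[["A"]]; B <- 2 * cnt[["B"]]  # ordered-pair counts
  if (A == 0 || B == 0)
    return(structure(NA_real_, valid = FALSE, n = n, r = r, A = A, B = B,
                     reason = "no template matches"))
  structure(-log(A / B), valid = TRUE, degenerate = FALSE, n = n, r = r,
            A = A, B = B)
}

#' All three entropy measures for one signal
#'
#' @inheritParams shannon_entropy
#' @return One-row data.frame with `shannon` (bits), `apen` (nats),
#'   `sampen` (nats), `n_shannon`, `n_template`, `shannon_valid`,
#'   `apen_valid`, `sampen_valid`, `A`, `B`.
#' @export
entropy_summary <- function(x, params = entropy_params()) {
  h <- shannon_entropy(x, params)
  ap <- approximate_entropy(x, params)
  sp <- sample_entropy(x, params)
  nsh <- sum(is.finite(if (inherits(x, "sampled_signal")) x$samples else x))
  data.frame(shannon = as.numeric(h), apen = as.numeric(ap),
             sampen = as.numeric(sp),
             n_shannon = nsh,
             n_template = if (!is.null(attr(ap, "n"))) attr(ap, "n") else NA_integer_,
             shannon_valid = isTRUE(attr(h, "valid")),
             apen_valid = isTRUE(attr(ap, "valid")),
             sampen_valid = isTRUE(attr(sp, "valid")),
             A = if (!is.null(attr(sp, "A"))) attr(sp, "A") else NA_real_,
             B = if (!is.null(attr(sp, "B"))) attr(sp, "B") else NA_real_)
}
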