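#' Spectral-analysis parameters
#'
#' Welch power-spectral-density settings: Hamming windows of 2048 samples
#' with 50% overlap, and the 30-1000 Hz analysis band whose 30 Hz floor
#' excludes ECG contamination concentrated at lower frequencies.
#'
#' @param window_len Segment length in samples (>= 64).
#' @param overlap_frac Fractional overlap between segments, in [0, 1).
#' @param band Analysis band `c(low, high)` in Hz.
#' @return An object of class `spectral_params`.
#' @export
spectral_params <- function(window_len = 2048, overlap_frac = 0.5,
                            band = c(30, 1000)) {
  if (window_len < 64) stop("window_len must be >= 64")
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap_frac must be in [0, 1)")
  if (band[1] <= 0 || band[2] <= band[1]) stop("band must satisfy 0 < low < high")
  structure(list(window_len = window_len, overlap_frac = overlap_frac,
                 band = band), class = "spectral_params")
}

#' Welch power-spectral-density estimate
#'
#' Averaged modified periodograms over Hamming-windowed, overlapping,
#' mean-removed segments. If the signal is shorter than `window_len`, a
#' single segment of the full available length is used. The one-sided PSD
#' is density-scaled, so its integral over frequency matches the
#' time-domain mean square of the (mean-removed) signal.
#'
#' @param x A [sampled_signal], or a numeric vector with `rate` given.
#' @param params A [spectral_params()].
#' @param rate Sampling rate in Hz (only if `x` is a bare vector).
#' @return A list of class `welch_psd` with `freq` (Hz), `psd`
#'   (amplitude-units squared per Hz), `n_segments`, `rate`,
#'   `window_len`.
#' @export
welch_psd <- function(x, params = spectral_params(), rate = NULL) {
  if (inherits(x, "sampled_signal")) { rate <- x$rate; x <- x$samples }
  if (is.null(rate)) stop("rate required for bare numeric input")
  n <- length(x)
  if (n < 64) stop("signal shorter than 64 samples")
  wl <- min(params$window_len, n)
  hop <- max(1L, round(wl * (1 - params$overlap_frac)))
  starts <- seq(1L, n - wl + 1L, by = hop)
  w <- hamming_window(wl)
  u <- sum(w^2)
  nfreq <- wl %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + wl - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + Mod(X)^2
  }
  pxx <- acc / (length(starts) * rate * u)
  # one-sided: double everything except DC (and Nyquist when wl is even)
  scale2 <- rep(2, nfreq); scale2[1] <- 1
  if (wl %% 2 == 0) scale2[nfreq] <- 1
  structure(list(freq = (seq_len(nfreq) - 1) * rate / wl,
                 psd = pxx * scale2,
                 n_segments = length(starts), rate = rate, window_len = wl),
            class = "welch_psd")
}

hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' @export
print.welch_psd <- function(x, ...) {
  cat(sprintf("<welch_psd> %d bins to %g Hz (resolution %.3g Hz), %d segment(s)\n",
              length(x$freq), max(x$freq), x$rate / x$window_len, x$n_segments))
  invisible(x)
}

#' @export
plot.welch_psd <- function(x, log = "y", xlab = "Frequency (Hz)",
                           ylab = "PSD", type = "l", ...) {
  keep <- if (log %in% c("y", "xy")) x$psd > 0 else TRUE
  graphics::plot(x$freq[keep], x$psd[keep], log = log, xlab = xlab,
                 ylab = ylab, type = type, ...)
  invisible(x)
}

#' Spectrum parameters over an analysis band
#'
#' Restricts the PSD to the analysis band and computes the mean frequency
#' (power-weighted average), median frequency (first bin at which the
#' cumulative trapezoidal power reaches half the band total), maximum
#' frequency (bin of peak power; earliest bin on ties), the power at each
#' of those bins, and total band power by trapezoidal integration.
#'
#' @param psd A `welch_psd` object, or a list with `freq` and `psd`.
#' @param band Analysis band `c(low, high)` in Hz.
#' @return A one-row data.frame of class `spectrum_summary`: `mean_freq`,
#'   `power_at_mean`, `median_freq`, `power_at_median`, `max_freq`,
#'   `power_at_max`, `total_power`, `n_segments`, `valid`. For an
#'   all-zero band the frequencies are `NaN`, `total_power` is 0 and
#'   `valid` is `FALSE`.
#' @export
spectrum_params <- function(psd, band = c(30, 1000)) {
  f <- psd$freq; p <- psd$psd
  if (is.unsorted(f, strictly = TRUE)) stop("frequencies must be strictly increasing")
  if (length(p) != length(f)) stop("freq and psd lengths differ")
  if (any(p < 0)) stop("psd must be non-negative")
  keep <- f >= band[1] & f <= band[2]
  fb <- f[keep]; pb <- p[keep]
  nseg <- if (!is.null(psd$n_segments)) psd$n_segments else NA_integer_
  if (length(fb) == 0 || sum(pb) == 0) {
    out <- data.frame(mean_freq = NaN, power_at_mean = NaN,
                      median_freq = NaN, power_at_median = NaN,
                      max_freq = NaN, power_at_max = NaN,
                      total_power = 0, n_segments = nseg, valid = FALSE)
    class(out) <- c("spectrum_summary", "data.frame")
    return(out)
  }
  mean_freq <- sum(fb * pb) / sum(pb)
  i_mean <- which.min(abs(fb - mean_freq))
  cum <- c(0, cumsum((fb[-1] - fb[-length(fb)]) *
                       (pb[-1] + pb[-length(pb)]) / 2))
  total <- cum[length(cum)]
  i_med <- which(cum >= total / 2)[1]
  i_max <- which.max(pb)  # earliest bin on ties
  out <- data.frame(mean_freq = mean_freq, power_at_mean = pb[i_mean],
                    median_freq = fb[i_med], power_at_median = pb[i_med],
                    max_freq = fb[i_max], power_at_max = pb[i_max],
                    total_power = total, n_segments = nseg, valid = TRUE)
  class(out) <- c("spectrum_summary", "data.frame")
  out
}
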