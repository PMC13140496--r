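#' Rectified moving-average EMG envelope
#'
#' Full-wave rectification followed by a centred moving average — the
#' "integrated EMG" trace used for burst amplitude, neural respiratory
#' drive and rise-time measures. The default 50 ms window resolves mouse
#' inspiratory bursts (~100-300 ms) while smoothing individual spikes.
#'
#' @param x A filtered EMG [sampled_signal].
#' @param window Averaging window in seconds (> 1 sample).
#' @return A [sampled_signal] envelope in the input units.
#' @export
emg_envelope <- function(x, window = 0.05) {
  w <- round(window * x$rate)
  if (w < 1) stop("envelope window shorter than one sample")
  r <- abs(x$samples)
  n <- length(r)
  if (w == 1) return(sampled_signal(r, x$rate, x$label, x$units, t0 = x$t0))
  # centred moving average via cumulative sums; edges use the available span
  half_lo <- (w - 1) %/% 2
  half_hi <- w %/% 2
  cs <- cumsum(c(0, r))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  env <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  sampled_signal(env, x$rate, x$label, x$units, t0 = x$t0)
}

#' Per-breath time-integral of rectified EMG
#'
#' Trapezoidal integral of the rectified (filtered) EMG from breath onset
#' to offset, in uV.s — the denominator of neuromechanical efficiency.
#'
#' @param x A filtered EMG [sampled_signal] (rectification is applied
#'   here).
#' @param onset_time,offset_time Breath interval bounds in seconds.
#' @return Integral in uV.s (non-negative).
#' @export
breath_emg_integral <- function(x, onset_time, offset_time) {
  if (offset_time <= onset_time) stop("empty breath interval")
  seg <- signal_window(x, onset_time, offset_time)
  r <- abs(seg$samples)
  if (length(r) < 2) stop("breath interval contains fewer than 2 samples")
  trapz_uniform(r, 1 / seg$rate)
}

# trapezoid rule on a uniform grid with spacing dx
trapz_uniform <- function(y, dx) {
  n <- length(y)
  if (n < 2) return(0)
  dx * (sum(y) - (y[1] + y[n]) / 2)
}

# trapezoid rule on an arbitrary grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}
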