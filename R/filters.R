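#' EMG filter specification
#'
#' Defaults follow standard practice for rodent respiratory EMG: a 50 Hz
#' notch (quality factor 35) to remove mains interference, and a
#' fourth-order Butterworth bandpass over 30-1000 Hz isolating the
#' physiologically relevant myoelectric band (the 30 Hz floor also rejects
#' most ECG contamination).
#'
#' @param notch_freq Notch centre frequency in Hz.
#' @param notch_q Notch quality factor (centre / -3 dB bandwidth).
#' @param band_low,band_high Bandpass corner frequencies in Hz.
#' @param order Butterworth order (even, >= 2).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(notch_freq = 50, notch_q = 35,
                        band_low = 30, band_high = 1000, order = 4) {
  if (!(band_low > 0 && band_low < band_high)) stop("need 0 < band_low < band_high")
  if (notch_q <= 0) stop("notch_q must be > 0")
  if (order < 2 || order %% 2 != 0) stop("order must be even and >= 2")
  structure(list(notch_freq = notch_freq, notch_q = notch_q,
                 band_low = band_low, band_high = band_high, order = order),
            class = "filter_spec")
}

# Pole-magnitude stability test: all poles strictly inside the unit
# circle with tolerance 1 - 1e-9.
is_stable_tf <- function(a) {
  if (length(a) <= 1) return(TRUE)
  all(Mod(polyroot(rev(a))) < 1 - 1e-9)
}

# RBJ biquad notch at f0 with quality factor Q.
design_notch <- function(f0, Q, rate) {
  w0 <- 2 * pi * f0 / rate
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

# Analytic Butterworth bandpass in second-order sections.
#
# The analog prototype poles are known in closed form; the
# lowpass->bandpass transform and the bilinear transform (with corner
# prewarping) are applied pole by pole, so the high-order transfer
# polynomial - whose rooting is what destabilises the naive design - is
# never formed. Each conjugate pole pair becomes one biquad with zeros
# at z = +1 and z = -1.
butter_bandpass_sos <- function(order, band_low, band_high, rate) {
  n <- order
  fs2 <- 2 * rate
  w1 <- fs2 * tan(pi * band_low / rate)
  w2 <- fs2 * tan(pi * band_high / rate)
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # left-half-plane, |p| = 1
  # lowpass -> bandpass: each prototype pole maps to a quadratic pair
  half <- proto * bw / 2
  disc <- sqrt(half^2 - w0^2)
  s_poles <- c(half + disc, half - disc)
  z_poles <- (fs2 + s_poles) / (fs2 - s_poles)     # bilinear
  # the pole set is closed under conjugation: one biquad per upper-half-
  # plane pole (paired with its conjugate); any real poles pair up after
  # sorting. Zeros at z = +1 and z = -1 give numerator z^2 - 1.
  cplx <- z_poles[Im(z_poles) > 1e-12]
  reals <- sort(Re(z_poles[abs(Im(z_poles)) <= 1e-12]))
  cplx <- cplx[order(Mod(cplx), Arg(cplx))]
  secs <- lapply(cplx, function(p) c(1, -2 * Re(p), Mod(p)^2))
  if (length(reals) %% 2 != 0) stop("internal: unpaired real pole")
  if (length(reals) > 0)
    for (i in seq(1, length(reals), by = 2))
      secs <- c(secs, list(c(1, -(reals[i] + reals[i + 1]), reals[i] * reals[i + 1])))
  sos <- do.call(rbind, lapply(secs, function(a2) c(1, 0, -1, a2)))
  # normalise overall gain to 1 at the (prewarped) centre frequency
  fc <- rate * atan(w0 / fs2) / pi
  g <- Mod(sos_response(sos, fc, rate))
  sos[1, 1:3] <- sos[1, 1:3] / g
  sos
}

# Complex frequency response of an SOS cascade at frequencies f (Hz).
sos_response <- function(sos, f, rate) {
  z <- exp(2i * pi * f / rate)
  h <- rep(1 + 0i, length(f))
  for (r in seq_len(nrow(sos))) {
    num <- sos[r, 1] + sos[r, 2] / z + sos[r, 3] / z^2
    den <- sos[r, 4] + sos[r, 5] / z + sos[r, 6] / z^2
    h <- h * num / den
  }
  h
}

# Complex frequency response of a transfer-function filter at f (Hz).
tf_response <- function(b, a, f, rate) {
  z <- exp(2i * pi * f / rate)
  num <- vapply(z, function(zz) sum(b * zz^-(seq_along(b) - 1)), complex(1))
  den <- vapply(z, function(zz) sum(a * zz^-(seq_along(a) - 1)), complex(1))
  num / den
}

#' Design the notch + bandpass filter set for a sampling rate
#'
#' The Butterworth bandpass is designed in transfer-function form and its
#' poles checked for stability (all magnitudes < 1 - 1e-9). If the
#' transfer-function form is unstable - which happens for high orders or
#' narrow bands relative to the sampling rate - an analytically derived
#' second-order-section (SOS) cascade is used instead and the result is
#' flagged (`bandpass_form == "sos"`).
#'
#' @param spec A [filter_spec].
#' @param rate Sampling rate in Hz; `band_high` must be below `rate / 2`.
#' @return An object of class `filter_set` with elements `notch` (b, a),
#'   `bandpass` (b, a or an SOS matrix), `bandpass_form` (`"tf"` or
#'   `"sos"`), `spec` and `rate`.
#' @export
design_filters <- function(spec = filter_spec(), rate) {
  if (spec$band_high >= rate / 2) stop("band exceeds Nyquist")
  notch <- design_notch(spec$notch_freq, spec$notch_q, rate)
  ba <- signal::butter(spec$order,
                       c(spec$band_low, spec$band_high) / (rate / 2),
                       type = "pass")
  if (is_stable_tf(ba$a)) {
    bandpass <- list(b = as.numeric(ba$b), a = as.numeric(ba$a))
    form <- "tf"
  } else {
    bandpass <- butter_bandpass_sos(spec$order, spec$band_low,
                                    spec$band_high, rate)
    form <- "sos"
  }
  structure(list(notch = notch, bandpass = bandpass, bandpass_form = form,
                 spec = spec, rate = rate),
            class = "filter_set")
}

#' @export
print.filter_set <- function(x, ...) {
  cat(sprintf("<filter_set> rate %g Hz: notch %g Hz (Q=%g) + Butterworth order %d [%g, %g] Hz (%s form)\n",
              x$rate, x$spec$notch_freq, x$spec$notch_q, x$spec$order,
              x$spec$band_low, x$spec$band_high, x$bandpass_form))
  invisible(x)
}

#' Single-pass frequency response of a designed filter set
#'
#' @param filters A `filter_set` from [design_filters()].
#' @param f Frequencies in Hz.
#' @param which `"both"`, `"notch"` or `"bandpass"`.
#' @return Complex response at `f`. Zero-phase application via
#'   [apply_filters()] realises the squared magnitude of this response.
#' @export
filter_response <- function(filters, f, which = c("both", "notch", "bandpass")) {
  which <- match.arg(which)
  hn <- tf_response(filters$notch$b, filters$notch$a, f, filters$rate)
  hb <- if (filters$bandpass_form == "sos") {
    sos_response(filters$bandpass, f, filters$rate)
  } else {
    tf_response(filters$bandpass$b, filters$bandpass$a, f, filters$rate)
  }
  switch(which, both = hn * hb, notch = hn, bandpass = hb)
}

# forward-backward filtering of one (b, a) stage
filtfilt_ba <- function(b, a, x) as.numeric(signal::filtfilt(b, a, x))

#' Apply the filter set with zero phase
#'
#' Notch then bandpass, each applied forward-backward so that the output
#' has no phase distortion (burst onset and peak timing are preserved for
#' rise-time and drive-rate measures). The effective magnitude response is
#' the square of the single-pass response. SOS cascades are applied
#' section by section.
#'
#' @param x A [sampled_signal].
#' @param filters A `filter_set` designed for this signal's rate.
#' @return A filtered [sampled_signal] of identical length, label and
#'   units.
#' @export
apply_filters <- function(x, filters) {
  if (!inherits(x, "sampled_signal")) stop("x must be a sampled_signal")
  if (abs(filters$rate - x$rate) > 1e-6 * x$rate)
    stop("filter set designed for rate ", filters$rate,
         " Hz but signal is at ", x$rate, " Hz")
  na <- if (filters$bandpass_form == "sos") 3L else length(filters$bandpass$a)
  # practical transient length of the forward-backward pass
  if (length(x$samples) < 9L * max(na, length(filters$notch$a)))
    stop("signal too short to filter")
  y <- filtfilt_ba(filters$notch$b, filters$notch$a, x$samples)
  if (filters$bandpass_form == "sos") {
    for (r in seq_len(nrow(filters$bandpass)))
      y <- filtfilt_ba(filters$bandpass[r, 1:3], filters$bandpass[r, 4:6], y)
  } else {
    y <- filtfilt_ba(filters$bandpass$b, filters$bandpass$a, y)
  }
  sampled_signal(y, x$rate, x$label, x$units, t0 = x$t0)
}
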