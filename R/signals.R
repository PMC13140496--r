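#' Construct a uniformly sampled physiological signal
#'
#' A `sampled_signal` is one channel of uniformly sampled data: EMG in
#' microvolts (uV) or oesophageal pressure in centimetres of water (cmH2O),
#' together with its sampling rate and channel label.
#'
#' Non-finite samples are permitted at construction time; they are counted
#' and flagged (`n_nonfinite` attribute) rather than dropped, so that
#' artifact handling remains an explicit, later step.
#'
#' @param samples Numeric vector of amplitudes.
#' @param rate Sampling frequency in Hz (> 0).
#' @param label Channel name; conventionally one of `"dia"`, `"eic"`,
#'   `"ps"` (EMG) or `"pressure"`.
#' @param units Unit string, e.g. `"uV"` or `"cmH2O"`.
#' @param t0 Time of the first sample in seconds (default 0).
#'
#' @return An object of class `sampled_signal`.
#' @export
sampled_signal <- function(samples, rate, label = "dia", units = "uV", t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate must be a single positive number")
  if (length(samples) < 1L) stop("samples must have length >= 1")
  structure(
    list(samples = samples, rate = rate, label = label, units = units, t0 = t0),
    n_nonfinite = sum(!is.finite(samples)),
    class = "sampled_signal"
  )
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %s [%s], %d samples at %g Hz (%.3f s)\n",
              x$label, x$units, length(x$samples), x$rate,
              length(x$samples) / x$rate))
  nf <- attr(x, "n_nonfinite")
  if (!is.null(nf) && nf > 0) cat(sprintf("  %d non-finite samples flagged\n", nf))
  invisible(x)
}

#' @export
length.sampled_signal <- function(x) length(x$samples)

#' Signal duration in seconds
#' @param x A `sampled_signal`.
#' @return Duration in seconds.
#' @export
signal_duration <- function(x) length(x$samples) / x$rate

#' Sample times of a signal
#' @param x A `sampled_signal`.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) x$t0 + (seq_along(x$samples) - 1) / x$rate

#' Extract the samples falling inside a time interval
#'
#' @param x A `sampled_signal`.
#' @param start,end Interval bounds in seconds (both inclusive, so that
#'   time integrals over `[start, end]` cover the full span).
#' @return A `sampled_signal` covering the interval, with `t0` set to the
#'   time of its first sample.
#' @export
signal_window <- function(x, start, end) {
  if (end <= start) stop("empty interval")
  i0 <- max(1L, ceiling((start - x$t0) * x$rate - 1e-9) + 1L)
  i1 <- min(length(x$samples), floor((end - x$t0) * x$rate + 1e-9) + 1L)
  if (i1 < i0) stop("interval outside signal")
  sampled_signal(x$samples[i0:i1], x$rate, x$label, x$units,
                 t0 = x$t0 + (i0 - 1) / x$rate)
}

#' Behavioural-state interval table
#'
#' Builds the table of labelled behavioural-state intervals for a
#' recording: baseline, post-vagotomy, hypercapnic hypoxia (hchx) and
#' sustained tracheal occlusion.
#'
#' @param state Character vector of states, each one of `"baseline"`,
#'   `"post_vagotomy"`, `"hchx"`, `"occlusion"`.
#' @param start,end Numeric vectors of interval bounds in seconds.
#' @return A `data.frame` with columns `state`, `start`, `end`.
#' @export
state_intervals <- function(state, start, end) {
  valid <- c("baseline", "post_vagotomy", "hchx", "occlusion")
  state <- as.character(state)
  if (!all(state %in% valid))
    stop("unknown state(s): ", paste(setdiff(state, valid), collapse = ", "))
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0) || any(end <= start))
    stop("state intervals require 0 <= start < end")
  ord <- order(start)
  st <- data.frame(state = state[ord], start = start[ord], end = end[ord],
                   stringsAsFactors = FALSE)
  if (nrow(st) > 1 && any(st$start[-1] < st$end[-nrow(st)] - 1e-9))
    stop("state intervals overlap")
  st
}

#' Assemble a multi-channel recording
#'
#' A `recording` bundles a set of channels (each a [sampled_signal], with
#' possibly different rates: EMG at 20 kHz, pressure at 1 kHz), the
#' behavioural-state interval table, and subject metadata. All channels
#' share a common time origin.
#'
#' @param channels Named list of [sampled_signal] objects; names must be
#'   unique and match each signal's label.
#' @param states A state-interval table from [state_intervals()].
#' @param subject_meta List with elements `id`, `genotype`, `age_months`.
#' @return An object of class `recording`.
#' @export
recording <- function(channels, states,
                      subject_meta = list(id = "s1", genotype = "wt",
                                          age_months = NA_real_)) {
  if (is.null(names(channels)) || anyDuplicated(names(channels)))
    stop("channels must be a uniquely named list")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!inherits(ch, "sampled_signal")) stop("channel ", nm, " is not a sampled_signal")
    if (!identical(ch$label, nm)) channels[[nm]]$label <- nm
  }
  if (nrow(states) > 0) {
    dur <- vapply(channels, function(ch) ch$t0 + signal_duration(ch), numeric(1))
    if (any(states$end > min(dur) + 1e-6))
      stop("state interval extends beyond channel duration")
  }
  structure(list(channels = channels, states = states,
                 subject_meta = subject_meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s (%s, %s months)\n",
              x$subject_meta$id, x$subject_meta$genotype,
              format(x$subject_meta$age_months)))
  for (ch in x$channels)
    cat(sprintf("  %-9s %8d samples @ %6g Hz [%s]\n",
                ch$label, length(ch$samples), ch$rate, ch$units))
  if (nrow(x$states))
    cat("  states:", paste(sprintf("%s [%.2f, %.2f]", x$states$state,
                                   x$states$start, x$states$end),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Look up one state interval of a recording
#' @param rec A `recording`.
#' @param state State name.
#' @return One-row data.frame with `state`, `start`, `end`.
#' @export
get_state <- function(rec, state) {
  i <- which(rec$states$state == state)
  if (length(i) == 0) stop("recording has no '", state, "' interval")
  rec$states[i[1], , drop = FALSE]
}
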