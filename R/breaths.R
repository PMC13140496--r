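#' Breath-segmentation specification
#'
#' Burst onsets are detected at upward crossings of an adaptive threshold
#' (baseline median + `threshold_k` baseline standard deviations, both
#' estimated from the quietest decile of 200 ms windows in the analysed
#' interval); offsets at the subsequent downward crossing of
#' `hysteresis_frac` times the threshold. Bursts closer than
#' `min_separation` are merged, then bursts shorter than `min_ti` are
#' discarded.
#'
#' @param threshold_k Onset threshold in multiples of the baseline SD.
#' @param hysteresis_frac Offset threshold as a fraction of the onset
#'   threshold (0-1).
#' @param min_ti Minimum burst duration in seconds.
#' @param min_separation Minimum gap between bursts in seconds.
#' @return An object of class `segmentation_spec`.
#' @export
segmentation_spec <- function(threshold_k = 3, hysteresis_frac = 0.5,
                              min_ti = 0.03, min_separation = 0.05) {
  if (threshold_k <= 0) stop("threshold_k must be > 0")
  if (hysteresis_frac <= 0 || hysteresis_frac >= 1)
    stop("hysteresis_frac must be in (0, 1)")
  structure(list(threshold_k = threshold_k, hysteresis_frac = hysteresis_frac,
                 min_ti = min_ti, min_separation = min_separation),
            class = "segmentation_spec")
}

# Baseline statistics from the quietest decile of 200 ms windows.
# Quietness is scored by mean deviation from the global median (level,
# not within-window SD: a smoothed envelope's quiet windows have tiny
# internal SD, which would underestimate the baseline variability).
# Returns list(median, sd) pooled over the samples of those windows.
quiet_baseline <- function(x, rate, win_s = 0.2) {
  w <- max(2L, round(win_s * rate))
  n <- length(x)
  nwin <- n %/% w
  if (nwin < 2) return(list(median = stats::median(x), sd = stats::sd(x)))
  idx <- seq_len(nwin * w)
  mat <- matrix(x[idx], nrow = w)
  dev <- colMeans(abs(mat - stats::median(x)))
  keep <- which(dev <= stats::quantile(dev, 0.1, names = FALSE))
  quiet <- as.numeric(mat[, keep, drop = FALSE])
  list(median = stats::median(quiet), sd = stats::sd(quiet))
}

#' Detect respiratory efforts in an envelope or pressure trace
#'
#' Segments individual respiratory efforts from either an EMG envelope or
#' an (oesophageal) pressure channel. Inspiratory pressure deflections are
#' sub-atmospheric, so pressure is analysed as the magnitude of the
#' deviation below the running zero-flow baseline; envelopes are analysed
#' as-is. The detection threshold is data-adaptive (see
#' [segmentation_spec()]), which makes the detected breath count invariant
#' to uniform amplitude scaling.
#'
#' @param x A [sampled_signal]: EMG envelope or pressure.
#' @param interval Optional one-row data.frame (or list) with `start` and
#'   `end` in seconds; default is the whole signal.
#' @param spec A [segmentation_spec()].
#' @param channel_kind `"auto"` (pressure channels by label), `"envelope"`
#'   or `"pressure"`.
#' @return A data.frame of class `breath_table`: one row per detected
#'   breath with `onset_time`, `peak_time`, `offset_time`, `ti`, `ttot`
#'   (onset-to-next-onset; `NA` for the last breath), `duty_cycle`,
#'   `peak_value` (peak envelope in uV, or peak inspiratory deflection
#'   magnitude in cmH2O), and `source_channel`.
#' @export
detect_breaths <- function(x, interval = NULL, spec = segmentation_spec(),
                           channel_kind = c("auto", "envelope", "pressure")) {
  channel_kind <- match.arg(channel_kind)
  if (channel_kind == "auto")
    channel_kind <- if (identical(x$label, "pressure")) "pressure" else "envelope"
  if (is.null(interval))
    interval <- list(start = x$t0, end = x$t0 + signal_duration(x))
  if (interval$end - interval$start < 0.5) stop("interval too short")
  seg <- signal_window(x, interval$start, interval$end)
  base <- quiet_baseline(seg$samples, seg$rate)
  d <- if (channel_kind == "pressure") base$median - seg$samples else seg$samples
  base_d <- if (channel_kind == "pressure") {
    list(median = 0, sd = base$sd)
  } else base
  thr <- base_d$median + spec$threshold_k * base_d$sd
  if (!is.finite(thr) || base_d$sd == 0) thr <- base_d$median + 1e-12
  off_thr <- base_d$median + spec$hysteresis_frac * (thr - base_d$median)

  above <- d > thr
  rises <- which(diff(c(FALSE, above)) == 1)
  bursts <- list()
  for (i0 in rises) {
    # offset: first downward crossing of the hysteresis threshold after i0
    below <- which(d[i0:length(d)] < off_thr)
    i1 <- if (length(below)) i0 + below[1] - 2L else length(d)
    if (length(bursts) && i0 <= bursts[[length(bursts)]][2]) next
    bursts[[length(bursts) + 1]] <- c(i0, i1)
  }
  if (length(bursts) == 0) return(empty_breath_table(x$label))

  # merge bursts separated by less than min_separation
  merged <- list(bursts[[1]])
  if (length(bursts) > 1) {
    for (b in bursts[-1]) {
      last <- merged[[length(merged)]]
      if ((b[1] - last[2]) / seg$rate < spec$min_separation) {
        merged[[length(merged)]] <- c(last[1], b[2])
      } else merged[[length(merged) + 1]] <- b
    }
  }
  # discard bursts shorter than min_ti
  dur <- vapply(merged, function(b) (b[2] - b[1] + 1) / seg$rate, numeric(1))
  merged <- merged[dur >= spec$min_ti]
  if (length(merged) == 0) return(empty_breath_table(x$label))

  t_of <- function(i) seg$t0 + (i - 1) / seg$rate
  rows <- lapply(merged, function(b) {
    ipk <- b[1] + which.max(d[b[1]:b[2]]) - 1L   # earliest max on ties
    data.frame(onset_time = t_of(b[1]), peak_time = t_of(ipk),
               offset_time = t_of(b[2]), peak_value = d[ipk])
  })
  br <- do.call(rbind, rows)
  br$ti <- br$offset_time - br$onset_time
  br$ttot <- c(diff(br$onset_time), NA_real_)
  br$duty_cycle <- br$ti / br$ttot
  br$source_channel <- x$label
  br <- br[, c("onset_time", "peak_time", "offset_time", "ti", "ttot",
               "duty_cycle", "peak_value", "source_channel")]
  attr(br, "baseline") <- base$median   # original-signal units
  attr(br, "threshold") <- thr          # deflection/envelope units
  class(br) <- c("breath_table", "data.frame")
  br
}

empty_breath_table <- function(label) {
  br <- data.frame(onset_time = numeric(0), peak_time = numeric(0),
                   offset_time = numeric(0), ti = numeric(0),
                   ttot = numeric(0), duty_cycle = numeric(0),
                   peak_value = numeric(0),
                   source_channel = character(0))
  class(br) <- c("breath_table", "data.frame")
  br
}

#' Per-breath timing summary
#'
#' Recomputes Ti, Ttot (onset-to-next-onset) and the inspiratory duty
#' cycle Ti/Ttot for a breath table. The last breath has no following
#' onset, so its Ttot and duty cycle are undefined and excluded.
#'
#' @param breaths A `breath_table` from [detect_breaths()].
#' @return Data.frame with `ti`, `ttot`, `duty_cycle`, one row per breath
#'   with a defined cycle.
#' @export
breath_timing <- function(breaths) {
  if (nrow(breaths) < 2) {
    warning("fewer than 2 breaths: timing undefined")
    return(data.frame(ti = numeric(0), ttot = numeric(0),
                      duty_cycle = numeric(0)))
  }
  ttot <- diff(breaths$onset_time)
  ti <- breaths$ti[-nrow(breaths)]
  data.frame(ti = ti, ttot = ttot, duty_cycle = ti / ttot)
}

#' Onset-to-peak slope of a breath
#'
#' The slope of the inspiratory pressure (inspiratory drive rate,
#' cmH2O/s) or of the integrated EMG envelope (EMG rise slope, uV/s) from
#' breath onset to breath peak, as the two-point endpoint slope
#' (value at peak - value at onset) / (peak time - onset time).
#'
#' For pressure channels the value is the inspiratory deflection
#' magnitude below `baseline`, so a genuine effort has a non-negative
#' slope.
#'
#' @param x A [sampled_signal] (envelope or pressure).
#' @param breath One row of a `breath_table` (or a list with
#'   `onset_time` and `peak_time`).
#' @param channel_kind As in [detect_breaths()].
#' @param baseline Zero-flow pressure baseline (pressure channels only);
#'   default 0.
#' @return Slope in units/s.
#' @export
onset_to_peak_slope <- function(x, breath,
                                channel_kind = c("auto", "envelope", "pressure"),
                                baseline = 0) {
  channel_kind <- match.arg(channel_kind)
  if (channel_kind == "auto")
    channel_kind <- if (identical(x$label, "pressure")) "pressure" else "envelope"
  if (breath$peak_time <= breath$onset_time) stop("degenerate breath")
  v <- function(tt) {
    i <- round((tt - x$t0) * x$rate) + 1L
    i <- min(max(i, 1L), length(x$samples))
    s <- x$samples[i]
    if (channel_kind == "pressure") baseline - s else s
  }
  (v(breath$peak_time) - v(breath$onset_time)) /
    (breath$peak_time - breath$onset_time)
}
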