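#' Per-effort pressures during sustained airway occlusion
#'
#' Segments each inspiratory effort of the sustained tracheal occlusion
#' from the pressure channel and represents it as one
#' (time, peak deflection magnitude) point — the pressure-time plot of
#' maximal non-ventilatory efforts to task failure.
#'
#' @param pressure The pressure [sampled_signal].
#' @param occlusion One-row data.frame/list with `start`, `end` of the
#'   occlusion interval in seconds.
#' @param spec A [segmentation_spec()].
#' @return An object of class `effort_series`: list with `effort_times`
#'   (s, relative to occlusion onset), `effort_peaks` (cmH2O
#'   magnitudes), `nadir_index` (index of the largest effort, earliest
#'   on ties), and the underlying `breaths` table. Failure detection and
#'   AUC are added by [detect_task_failure()] / [pressure_time_auc()].
#' @export
extract_efforts <- function(pressure, occlusion, spec = segmentation_spec()) {
  br <- detect_breaths(pressure, occlusion, spec, channel_kind = "pressure")
  if (nrow(br) < 3) stop("too few efforts for occlusion analysis")
  structure(list(effort_times = br$peak_time - occlusion$start,
                 effort_peaks = br$peak_value,
                 nadir_index = which.max(br$peak_value),
                 failure_index = NA_integer_,
                 no_failure = NA,
                 auc = NA_real_,
                 breaths = br),
            class = "effort_series")
}

#' @export
print.effort_series <- function(x, ...) {
  cat(sprintf("<effort_series> %d efforts, nadir %.2f cmH2O at effort %d\n",
              length(x$effort_peaks), x$effort_peaks[x$nadir_index],
              x$nadir_index))
  if (!is.na(x$failure_index))
    cat(sprintf("  task failure at effort %d%s\n", x$failure_index,
                if (isTRUE(x$no_failure)) " (no sustained decline observed)" else ""))
  if (!is.na(x$auc)) cat(sprintf("  pressure-time AUC %.2f cmH2O.s\n", x$auc))
  invisible(x)
}

#' Detect task failure in an occlusion effort series
#'
#' Task failure is the point at which pressure generation declines from
#' the sustained peak nadir: the first effort after the nadir at which
#' `k_consecutive` successive efforts all fall below `decline_frac` times
#' the nadir magnitude. If no such decline occurs, the last effort is
#' returned with the `no_failure` flag set.
#'
#' @param series An `effort_series` from [extract_efforts()].
#' @param decline_frac Decline threshold as a fraction of the nadir
#'   magnitude (default 0.9).
#' @param k_consecutive Number of successive sub-threshold efforts
#'   required (default 2).
#' @return The `effort_series` with `failure_index` and `no_failure`
#'   filled in.
#' @export
detect_task_failure <- function(series, decline_frac = 0.9, k_consecutive = 2) {
  pk <- series$effort_peaks
  n <- length(pk)
  if (n < 3) stop("too few efforts for occlusion analysis")
  thr <- decline_frac * pk[series$nadir_index]
  failure <- NA_integer_
  if (series$nadir_index < n) {
    for (i in (series$nadir_index + 1):n) {
      j <- i:min(i + k_consecutive - 1, n)
      if (length(j) == k_consecutive && all(pk[j] < thr)) { failure <- i; break }
    }
  }
  series$no_failure <- is.na(failure)
  series$failure_index <- if (is.na(failure)) n else failure
  series
}

#' Pressure-time AUC of an occlusion effort series
#'
#' Trapezoidal area under the per-effort (time, peak pressure) points
#' from the first effort through the task-failure effort, in cmH2O.s.
#'
#' @param series An `effort_series`; if task failure has not been
#'   detected yet, [detect_task_failure()] defaults are applied first.
#' @return The `effort_series` with `auc` filled in; a single effort
#'   yields 0 with a warning.
#' @export
pressure_time_auc <- function(series) {
  if (is.na(series$failure_index)) series <- detect_task_failure(series)
  k <- seq_len(series$failure_index)
  if (length(k) < 2) {
    warning("single effort: AUC undefined, returning 0")
    series$auc <- 0
    return(series)
  }
  series$auc <- trapz(series$effort_times[k], series$effort_peaks[k])
  series
}

#' Full occlusion analysis
#'
#' Convenience wrapper: [extract_efforts()], [detect_task_failure()] and
#' [pressure_time_auc()] in sequence.
#'
#' @inheritParams extract_efforts
#' @inheritParams detect_task_failure
#' @return A completed `effort_series`.
#' @export
analyze_occlusion <- function(pressure, occlusion, spec = segmentation_spec(),
                              decline_frac = 0.9, k_consecutive = 2) {
  series <- extract_efforts(pressure, occlusion, spec)
  series <- detect_task_failure(series, decline_frac, k_consecutive)
  pressure_time_auc(series)
}
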