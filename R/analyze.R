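#' Analysis configuration
#'
#' Bundles every stage's tunable parameters with their defaults:
#' filtering (`filters`), envelope window, breath segmentation
#' (`segmentation`, driven by the pressure channel by default since it is
#' present in every state including occlusion), Welch spectral settings,
#' entropy settings, and the occlusion task-failure rule.
#'
#' @param filters A [filter_spec()].
#' @param envelope_window Envelope moving-average window, seconds.
#' @param segmentation A [segmentation_spec()].
#' @param segment_channel `"pressure"` or an EMG channel label whose
#'   envelope drives breath detection.
#' @param spectral A [spectral_params()].
#' @param entropy An [entropy_params()].
#' @param occlusion_decline_frac,occlusion_k Task-failure rule (see
#'   [detect_task_failure()]).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(filters = filter_spec(),
                            envelope_window = 0.05,
                            segmentation = segmentation_spec(),
                            segment_channel = "pressure",
                            spectral = spectral_params(),
                            entropy = entropy_params(),
                            occlusion_decline_frac = 0.9,
                            occlusion_k = 2) {
  structure(list(filters = filters, envelope_window = envelope_window,
                 segmentation = segmentation,
                 segment_channel = segment_channel,
                 spectral = spectral, entropy = entropy,
                 occlusion_decline_frac = occlusion_decline_frac,
                 occlusion_k = occlusion_k),
            class = "analysis_config")
}

#' Analyse one recording end-to-end
#'
#' Filters each EMG channel (notch + bandpass, zero phase), builds
#' rectified moving-average envelopes, segments breaths per behavioural
#' state from the pressure channel (or a chosen envelope), computes
#' per-breath amplitudes, timings, slopes and EMG integrals, derives the
#' occlusion references (five-consecutive-effort EMG maximum per muscle;
#' MIP as the single largest effort), and produces per-breath and
#' per-state index tables (NRD, NME, TTI, inspiratory drive rate, EMG
#' rise slope), per-state Welch spectrum parameters (on the filtered EMG
#' in mV), per-state entropy measures, and the occlusion pressure-time
#' analysis.
#'
#' @param rec A [recording].
#' @param config An [analysis_config()].
#' @return An object of class `resp_analysis`: list of data.frames
#'   `per_breath`, `indices`, `spectra`, `entropy`, `occlusion`, plus
#'   `references` (per-muscle EMG maxima and MIP) and `effort_series`.
#' @export
analyze_recording <- function(rec, config = analysis_config()) {
  meta <- rec$subject_meta
  muscles <- setdiff(names(rec$channels), "pressure")
  if (length(muscles) == 0) stop("recording has no EMG channels")
  has_pressure <- "pressure" %in% names(rec$channels)

  filtered <- list(); envs <- list()
  for (m in muscles) {
    fset <- design_filters(config$filters, rec$channels[[m]]$rate)
    filtered[[m]] <- apply_filters(rec$channels[[m]], fset)
    envs[[m]] <- emg_envelope(filtered[[m]], config$envelope_window)
  }

  use_pressure <- identical(config$segment_channel, "pressure") && has_pressure
  driver <- if (use_pressure) rec$channels$pressure
            else envs[[intersect(c(config$segment_channel, muscles[1]),
                                 muscles)[1]]]

  # breath detection per state
  breaths_by_state <- list()
  for (i in seq_len(nrow(rec$states))) {
    st <- rec$states[i, ]
    br <- detect_breaths(driver, st, config$segmentation)
    if (nrow(br) == 0) {
      warning("no breaths detected in state '", st$state, "'")
      next
    }
    breaths_by_state[[st$state]] <- br
  }
  if (is.null(breaths_by_state$occlusion))
    stop("no occlusion efforts detected: reference maxima unavailable")

  # occlusion references
  occ_int <- get_state(rec, "occlusion")
  series <- analyze_occlusion(if (has_pressure) rec$channels$pressure else driver,
                              occ_int, config$segmentation,
                              config$occlusion_decline_frac, config$occlusion_k)
  occ_br <- series$breaths
  emg_max <- list()
  for (m in muscles) {
    pk <- vapply(seq_len(nrow(occ_br)), function(k)
      max(signal_window(envs[[m]], occ_br$onset_time[k],
                        occ_br$offset_time[k])$samples), numeric(1))
    occ_tab <- occ_br; occ_tab$peak_value <- pk
    emg_max[[m]] <- compute_emg_max(occ_tab)
  }
  mip <- max(occ_br$peak_value)

  # per-breath feature rows, long over muscles
  rows <- list()
  for (st_name in names(breaths_by_state)) {
    br <- breaths_by_state[[st_name]]
    base <- attr(br, "baseline")
    for (m in muscles) {
      for (k in seq_len(nrow(br))) {
        b <- br[k, ]
        env_seg <- signal_window(envs[[m]], b$onset_time, b$offset_time)
        ipk <- which.max(env_seg$samples)
        peak_env <- env_seg$samples[ipk]
        tpk_env <- env_seg$t0 + (ipk - 1) / env_seg$rate
        emg_rise <- if (tpk_env > b$onset_time)
          (peak_env - env_seg$samples[1]) / (tpk_env - b$onset_time) else NA_real_
        integral <- breath_emg_integral(filtered[[m]], b$onset_time,
                                        b$offset_time)
        p_amp <- if (use_pressure) b$peak_value else NA_real_
        idr <- if (use_pressure)
          onset_to_peak_slope(rec$channels$pressure, b, "pressure",
                              baseline = if (!is.null(base)) base else 0)
          else NA_real_
        rows[[length(rows) + 1]] <- data.frame(
          subject = meta$id, genotype = meta$genotype,
          age_months = meta$age_months, muscle = m, state = st_name,
          breath = k, onset_time = b$onset_time, ti = b$ti, ttot = b$ttot,
          duty_cycle = b$duty_cycle, pressure_amp = p_amp,
          peak_env = peak_env, emg_integral = integral,
          nrd = nrd(peak_env, as.numeric(emg_max[[m]])),
          nme = as.numeric(nme(p_amp, integral)),
          tti = if (use_pressure && is.finite(b$ttot))
            tti(p_amp, mip, b$ti, b$ttot) else NA_real_,
          idr = idr, emg_rise = emg_rise,
          stringsAsFactors = FALSE)
      }
    }
  }
  per_breath <- do.call(rbind, rows)

  # per-state medians
  agg <- function(df) data.frame(
    subject = df$subject[1], genotype = df$genotype[1],
    age_months = df$age_months[1], muscle = df$muscle[1],
    state = df$state[1],
    nrd = stats::median(df$nrd, na.rm = TRUE),
    nme = stats::median(df$nme, na.rm = TRUE),
    tti = stats::median(df$tti, na.rm = TRUE),
    idr = stats::median(df$idr, na.rm = TRUE),
    emg_rise = stats::median(df$emg_rise, na.rm = TRUE),
    ti = stats::median(df$ti, na.rm = TRUE),
    ttot = stats::median(df$ttot, na.rm = TRUE),
    duty_cycle = stats::median(df$duty_cycle, na.rm = TRUE),
    n_breaths = nrow(df), stringsAsFactors = FALSE)
  key <- interaction(per_breath$muscle, per_breath$state, drop = TRUE)
  indices <- do.call(rbind, lapply(split(per_breath, key), agg))
  indices <- indices[order(indices$subject, indices$muscle, indices$state), ]
  rownames(indices) <- NULL

  # per-state spectra and entropy on the filtered EMG
  sp_rows <- list(); en_rows <- list()
  for (i in seq_len(nrow(rec$states))) {
    st <- rec$states[i, ]
    for (m in muscles) {
      seg <- signal_window(filtered[[m]], st$start, st$end)
      seg_mv <- sampled_signal(seg$samples / 1000, seg$rate, m, "mV",
                               t0 = seg$t0)
      ss <- spectrum_params(welch_psd(seg_mv, config$spectral),
                            config$spectral$band)
      sp_rows[[length(sp_rows) + 1]] <- cbind(
        data.frame(subject = meta$id, genotype = meta$genotype,
                   age_months = meta$age_months, muscle = m,
                   state = st$state, stringsAsFactors = FALSE),
        as.data.frame(ss))
      en <- entropy_summary(seg, config$entropy)
      en_rows[[length(en_rows) + 1]] <- cbind(
        data.frame(subject = meta$id, genotype = meta$genotype,
                   age_months = meta$age_months, muscle = m,
                   state = st$state, stringsAsFactors = FALSE),
        en)
    }
  }
  spectra <- do.call(rbind, sp_rows); rownames(spectra) <- NULL
  entropy <- do.call(rbind, en_rows); rownames(entropy) <- NULL

  occlusion <- data.frame(
    subject = meta$id, genotype = meta$genotype,
    age_months = meta$age_months,
    effort = seq_along(series$effort_times),
    time_s = series$effort_times,
    peak_cmh2o = series$effort_peaks,
    nadir_index = series$nadir_index,
    failure_index = series$failure_index,
    no_failure = series$no_failure,
    auc_cmh2o_s = series$auc, mip_cmh2o = mip,
    stringsAsFactors = FALSE)

  structure(list(per_breath = per_breath, indices = indices,
                 spectra = spectra, entropy = entropy,
                 occlusion = occlusion,
                 references = list(emg_max = lapply(emg_max, as.numeric),
                                   mip = mip),
                 effort_series = series,
                 breaths_by_state = breaths_by_state),
            class = "resp_analysis")
}

#' @export
print.resp_analysis <- function(x, ...) {
  cat(sprintf("<resp_analysis> subject %s: %d breaths, %d muscle-state spectra\n",
              x$per_breath$subject[1],
              length(unique(paste(x$per_breath$state, x$per_breath$breath))),
              nrow(x$spectra)))
  cat(sprintf("  MIP %.2f cmH2O; occlusion failure at effort %d, AUC %.1f cmH2O.s\n",
              x$references$mip, x$effort_series$failure_index,
              x$effort_series$auc))
  invisible(x)
}

#' @export
summary.resp_analysis <- function(object, ...) {
  print(object)
  cat("\nPer-state index medians:\n")
  print(object$indices, digits = 3)
  invisible(object$indices)
}
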