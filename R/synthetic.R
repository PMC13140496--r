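#' Configuration for the synthetic-recording generator
#'
#' Defines the study conditions the generator emulates: urethane-
#' anaesthetised mouse respiratory EMG (20 kHz) and oesophageal pressure
#' (1 kHz) across four sequential behavioural states — baseline, post-
#' vagotomy (slower, deeper breathing), hypercapnic hypoxia (faster,
#' stronger drive) and a sustained tracheal occlusion of escalating
#' maximal efforts declining to task failure.
#'
#' Each inspiratory burst is a half-sine envelope (duration `ti`, period
#' `ttot`) modulating band-limited Gaussian noise over `emg_band`, on top
#' of a broadband EMG noise floor, with additive 50 Hz line interference
#' and a periodic biphasic ECG-like artifact. The pressure channel
#' couples to the expected rectified diaphragm burst (not the noisy EMG
#' realisation), so `nme_gain` is an exact ground truth: each breath's
#' inspiratory deflection magnitude equals `nme_gain` times the expected
#' rectified-EMG time integral of the diaphragm burst.
#'
#' @param seed Integer RNG seed; a fixed seed makes the output
#'   bit-identical across calls.
#' @param rate_emg,rate_pressure Sampling rates in Hz.
#' @param n_breaths Breaths per tidal state.
#' @param ti,ttot Inspiratory and total cycle time in seconds (tidal
#'   baseline; ~150 breaths/min, duty cycle 0.4).
#' @param burst_amp Named peak envelope amplitudes in uV per muscle.
#' @param emg_band Band of the myoelectric noise carrier, Hz.
#' @param nme_gain Pressure per unit integrated diaphragm EMG
#'   (cmH2O per uV.s).
#' @param genotype_scale EMG amplitude scaling factor (1 = wild-type-
#'   like; < 1 = dystrophic-like reduction of myoelectric output).
#' @param line_noise_amp 50 Hz line interference amplitude, uV.
#' @param ecg_amp,ecg_rate ECG-artifact amplitude (uV) and rate (Hz;
#'   10 Hz ~ 600 bpm).
#' @param emg_noise_floor Broadband baseline EMG noise SD, uV.
#' @param cardiac_amp Amplitude of the periodic cardiac pressure
#'   artifact (a sinusoid at `ecg_rate`), cmH2O.
#' @param pressure_noise_sd SD of white pressure sensor noise, cmH2O.
#' @param vagotomy_amp_factor,vagotomy_ttot_factor Post-vagotomy burst
#'   amplitude and cycle-length multipliers.
#' @param hchx_amp_factor,hchx_ttot_factor Chemostimulation multipliers.
#' @param occlusion List: `n_efforts`, `escalation_frac` (first effort's
#'   amplitude as a fraction of the peak effort), `failure_onset_effort`
#'   (index at which decline begins), `failure_decline_frac` (per-effort
#'   multiplicative decline after onset), `effort_period` (s),
#'   `amp_factor` (peak maximal-effort amplitude as a multiple of the
#'   tidal burst amplitude).
#' @param subject_id,genotype,age_months Subject metadata.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             rate_emg = 20000, rate_pressure = 1000,
                             n_breaths = 10,
                             ti = 0.16, ttot = 0.40,
                             burst_amp = c(dia = 40, eic = 25, ps = 20),
                             emg_band = c(30, 1000),
                             nme_gain = 2.5,
                             genotype_scale = 1.0,
                             line_noise_amp = 5, ecg_amp = 20, ecg_rate = 10,
                             emg_noise_floor = 2,
                             cardiac_amp = 0.15,
                             pressure_noise_sd = 0.05,
                             vagotomy_amp_factor = 1.3,
                             vagotomy_ttot_factor = 1.5,
                             hchx_amp_factor = 1.6,
                             hchx_ttot_factor = 0.8,
                             occlusion = list(n_efforts = 16,
                                              escalation_frac = 0.3,
                                              failure_onset_effort = 12,
                                              failure_decline_frac = 0.85,
                                              effort_period = 0.5,
                                              amp_factor = 3),
                             subject_id = "sim1", genotype = "wt",
                             age_months = 8) {
  if (ti >= ttot) stop("ti must be < ttot")
  if (emg_band[1] <= 0 || emg_band[2] >= rate_emg / 2)
    stop("emg_band outside (0, rate/2)")
  amps <- c(burst_amp, nme_gain, genotype_scale, line_noise_amp, ecg_amp,
            emg_noise_floor, cardiac_amp, pressure_noise_sd)
  if (any(amps < 0)) stop("amplitudes must be >= 0")
  cfg <- as.list(environment())
  structure(cfg, class = "generator_config")
}

#' Band-limited Gaussian noise
#'
#' Unit-variance Gaussian noise whose spectrum is flat inside `band` and
#' zero outside (brick-wall shaping in the frequency domain). Used as the
#' myoelectric carrier of the generator and as a flat-spectrum test
#' signal.
#'
#' @param n Number of samples.
#' @param rate Sampling rate in Hz.
#' @param band `c(low, high)` in Hz.
#' @return Numeric vector of length `n` with sample SD 1.
#' @export
band_limited_noise <- function(n, rate, band = c(30, 1000)) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f)  # two-sided frequency magnitude
  X[f < band[1] | f > band[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

# half-sine burst envelope evaluated on times tt
half_sine_burst <- function(tt, onset, ti, amp) {
  inside <- tt >= onset & tt <= onset + ti
  out <- numeric(length(tt))
  out[inside] <- amp * sin(pi * (tt[inside] - onset) / ti)
  out
}

# occlusion effort amplitude profile, relative to the peak effort (= 1
# at effort failure_onset - 1): linear escalation, then multiplicative
# decline from failure_onset on
occlusion_profile <- function(occ) {
  n <- occ$n_efforts; f <- occ$failure_onset_effort
  s <- numeric(n)
  rise_end <- max(2L, f - 1L)
  s[1:rise_end] <- occ$escalation_frac +
    (1 - occ$escalation_frac) * (seq_len(rise_end) - 1) / (rise_end - 1)
  if (f <= n)
    s[f:n] <- occ$failure_decline_frac ^ (seq_len(n - f + 1))
  s
}

#' Generate a synthetic recording with ground truth
#'
#' Lays the four behavioural states out sequentially (separated by quiet
#' gaps), synthesises the three EMG channels and the coupled pressure
#' channel, and returns both the [recording] and a ground-truth object
#' carrying every configured parameter and the exact per-breath timing
#' and amplitudes, so that every pipeline stage can be checked against
#' what was generated.
#'
#' @param config A [generator_config()].
#' @return A list with elements `recording` (a [recording]) and `truth`
#'   (list: `config`, per-breath table `breaths` with state, onset/peak/
#'   offset times, per-muscle envelope amplitudes, expected diaphragm
#'   rectified-EMG integral and pressure amplitude; `occlusion` with
#'   per-effort times/amplitudes, configured failure-onset index and the
#'   closed-form pressure-time AUC through that effort; `states`).
#' @export
generate_recording <- function(config = generator_config()) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  occ <- config$occlusion
  gap <- 1.0; lead <- 0.2
  # state layout
  t0 <- 0.5
  len_base <- lead + config$n_breaths * config$ttot
  ttot_vag <- config$ttot * config$vagotomy_ttot_factor
  len_vag <- lead + config$n_breaths * ttot_vag
  ttot_hx <- config$ttot * config$hchx_ttot_factor
  len_hx <- lead + config$n_breaths * ttot_hx
  len_occ <- lead + occ$n_efforts * occ$effort_period
  starts <- cumsum(c(t0, len_base + gap, len_vag + gap, len_hx + gap))
  states <- state_intervals(
    c("baseline", "post_vagotomy", "hchx", "occlusion"),
    starts, starts + c(len_base, len_vag, len_hx, len_occ))
  total_dur <- starts[4] + len_occ + 0.5

  muscles <- names(config$burst_amp)
  # per-breath schedule: one row per breath, amplitude scale per state
  sched <- list(
    data.frame(state = "baseline",
               onset = starts[1] + lead + (seq_len(config$n_breaths) - 1) * config$ttot,
               ti = config$ti, scale = 1),
    data.frame(state = "post_vagotomy",
               onset = starts[2] + lead + (seq_len(config$n_breaths) - 1) * ttot_vag,
               ti = config$ti, scale = config$vagotomy_amp_factor),
    data.frame(state = "hchx",
               onset = starts[3] + lead + (seq_len(config$n_breaths) - 1) * ttot_hx,
               ti = config$ti, scale = config$hchx_amp_factor),
    data.frame(state = "occlusion",
               onset = starts[4] + lead + (seq_len(occ$n_efforts) - 1) * occ$effort_period,
               ti = config$ti,
               scale = occ$amp_factor * occlusion_profile(occ))
  )
  breaths <- do.call(rbind, sched)
  breaths$peak_time <- breaths$onset + breaths$ti / 2
  breaths$offset <- breaths$onset + breaths$ti
  for (m in muscles)
    breaths[[paste0("amp_", m)]] <- config$burst_amp[[m]] * breaths$scale *
      config$genotype_scale
  # expected rectified-EMG integral of the diaphragm burst as the
  # pipeline measures it: E|A sin * N(0,1)| integrated over ti gives
  # sqrt(2/pi) * A * (2/pi) * ti, times the rms fraction of the carrier
  # retained by the standard zero-phase physiological-band filter
  # (Butterworth corners sit AT the carrier band edges, so a few percent
  # of carrier power lies beyond the -3 dB points)
  rho <- filtered_carrier_fraction(config$emg_band, config$rate_emg)
  breaths$emg_integral <- rho * sqrt(2 / pi) *
    breaths[[paste0("amp_", muscles[1])]] * (2 / pi) * breaths$ti
  breaths$pressure_amp <- config$nme_gain * breaths$emg_integral

  # ---- EMG channels ----
  n_emg <- round(total_dur * config$rate_emg)
  tt <- (seq_len(n_emg) - 1) / config$rate_emg
  ecg <- ecg_train(tt, config$ecg_rate, config$ecg_amp)
  line <- config$line_noise_amp * sin(2 * pi * 50 * tt)
  channels <- list()
  for (m in muscles) {
    env <- numeric(n_emg)
    amps <- breaths[[paste0("amp_", m)]] / config$genotype_scale
    for (k in seq_len(nrow(breaths)))
      env <- env + half_sine_burst(tt, breaths$onset[k], breaths$ti[k], amps[k])
    carrier <- band_limited_noise(n_emg, config$rate_emg, config$emg_band)
    floor_n <- band_limited_noise(n_emg, config$rate_emg, config$emg_band)
    emg <- config$genotype_scale *
      (env * carrier + config$emg_noise_floor * floor_n) + line + ecg
    channels[[m]] <- sampled_signal(emg, config$rate_emg, m, "uV")
  }

  # ---- pressure channel ----
  n_pr <- round(total_dur * config$rate_pressure)
  tp <- (seq_len(n_pr) - 1) / config$rate_pressure
  pr <- numeric(n_pr)
  for (k in seq_len(nrow(breaths)))
    pr <- pr - half_sine_burst(tp, breaths$onset[k], breaths$ti[k],
                               breaths$pressure_amp[k])
  # periodic cardiac artifact plus white sensor noise
  pr <- pr + config$cardiac_amp * sin(2 * pi * config$ecg_rate * tp) +
    config$pressure_noise_sd * stats::rnorm(n_pr)
  channels$pressure <- sampled_signal(pr, config$rate_pressure, "pressure", "cmH2O")

  rec <- recording(channels, states,
                   subject_meta = list(id = config$subject_id,
                                       genotype = config$genotype,
                                       age_months = config$age_months))

  occ_rows <- breaths$state == "occlusion"
  occl_truth <- list(
    effort_times = breaths$peak_time[occ_rows] - starts[4],
    pressure_amps = breaths$pressure_amp[occ_rows],
    emg_amps = breaths[[paste0("amp_", muscles[1])]][occ_rows],
    failure_onset_effort = occ$failure_onset_effort,
    auc_closed_form = trapz(
      (breaths$peak_time[occ_rows] - starts[4])[seq_len(occ$failure_onset_effort)],
      breaths$pressure_amp[occ_rows][seq_len(occ$failure_onset_effort)])
  )
  list(recording = rec,
       truth = list(config = config, breaths = breaths,
                    occlusion = occl_truth, states = states))
}

# rms fraction of a flat-band unit carrier that survives the default
# zero-phase notch + bandpass whose corners match the carrier band
filtered_carrier_fraction <- function(band, rate) {
  fset <- design_filters(filter_spec(band_low = band[1], band_high = band[2]),
                         rate)
  f <- seq(band[1], band[2], length.out = 2000)
  sqrt(mean(Mod(filter_response(fset, f))^4))  # |H|^4: forward-backward power
}

# biphasic ECG-like pulse train: one 4 ms sine cycle per beat
ecg_train <- function(tt, rate, amp) {
  if (amp <= 0 || rate <= 0) return(numeric(length(tt)))
  width <- 0.004
  phase <- (tt + 0.017) %% (1 / rate)  # fixed offset desynchronises from breaths
  inside <- phase < width
  out <- numeric(length(tt))
  out[inside] <- amp * sin(2 * pi * phase[inside] / width)
  out
}
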