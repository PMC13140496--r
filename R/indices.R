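#' Reference maximum EMG from occlusion efforts
#'
#' The EMG reference maximum is the mean peak envelope over the window of
#' five consecutive peak efforts (during the single sustained tracheal
#' occlusion) with the largest mean; on ties the earliest window is used.
#' With fewer than five efforts the mean of all efforts is used and the
#' result carries a `fallback` flag.
#'
#' @param occlusion_breaths A `breath_table` of occlusion efforts whose
#'   `peak_value` column holds the per-effort peak EMG envelope (uV).
#' @param n_efforts Width of the consecutive-effort window (default 5).
#' @return EMG reference maximum in uV with attribute `fallback`.
#' @export
compute_emg_max <- function(occlusion_breaths, n_efforts = 5) {
  pk <- occlusion_breaths$peak_value
  if (length(pk) == 0) stop("no occlusion efforts: cannot compute EMG maximum")
  if (length(pk) < n_efforts) {
    warning("fewer than ", n_efforts,
            " occlusion efforts; using mean of all efforts")
    return(structure(mean(pk), fallback = TRUE))
  }
  means <- vapply(seq_len(length(pk) - n_efforts + 1),
                  function(i) mean(pk[i:(i + n_efforts - 1)]), numeric(1))
  structure(means[which.max(means)], fallback = FALSE)  # earliest on ties
}

#' Neural respiratory drive (NRD)
#'
#' Tidal EMG expressed as a percentage of the reference maximum EMG:
#' `NRD = EMG / EMG_max x 100`. Because numerator and reference scale
#' together, NRD is invariant to uniform amplitude scaling of the EMG
#' channel.
#'
#' @param peak_envelope Per-breath peak EMG envelope (uV).
#' @param emg_max Reference maximum EMG (uV, > 0).
#' @return NRD in percent.
#' @export
nrd <- function(peak_envelope, emg_max) {
  if (!is.finite(emg_max) || emg_max <= 0) stop("emg_max must be > 0")
  100 * peak_envelope / emg_max
}

#' Neuromechanical efficiency (NME)
#'
#' Inspiratory pressure generated per unit of integrated EMG activity:
#' `NME = Pressure / EMG`, in cmH2O per uV.s.
#'
#' @param pressure_amp Per-breath inspiratory deflection magnitude
#'   (cmH2O).
#' @param emg_integral Per-breath time-integral of rectified EMG (uV.s).
#' @return NME in cmH2O/(uV.s); `NA` with a `valid = FALSE` attribute for
#'   a silent muscle (zero integral).
#' @export
nme <- function(pressure_amp, emg_integral) {
  out <- ifelse(emg_integral > 0, pressure_amp / emg_integral, NA_real_)
  if (any(emg_integral <= 0)) attr(out, "valid") <- emg_integral > 0
  out
}

#' Tension-time index (TTI)
#'
#' `TTI = (P / MIP) x (Ti / Ttot)`: the product of relative inspiratory
#' pressure and inspiratory duty cycle; an index of respiratory muscle
#' fatigue risk.
#'
#' @param p Mean (per-breath) inspiratory pressure magnitude (cmH2O).
#' @param mip Maximal inspiratory pressure magnitude (cmH2O, > 0).
#' @param ti Inspiratory time (s).
#' @param ttot Total respiratory cycle time (s, > 0).
#' @return Dimensionless TTI.
#' @export
tti <- function(p, mip, ti, ttot) {
  if (any(!is.finite(mip)) || any(mip <= 0)) stop("mip must be > 0")
  if (any(!is.finite(ttot)) || any(ttot <= 0)) stop("ttot must be > 0")
  if (any(ti > ttot)) stop("ti exceeds ttot")
  (p / mip) * (ti / ttot)
}
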