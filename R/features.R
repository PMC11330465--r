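# Trapezoidal integral of y over samples i0..i1 at sampling interval dt.
trapz_win <- function(y, i0, i1, dt) {
  if (i1 <= i0) return(0)
  idx <- i0:i1
  sum((y[idx[-length(idx)]] + y[idx[-1]]) / 2) * dt
}

#' Extract the 17 per-cycle respiratory parameters
#'
#' Computes, for one expiration-inspiration cycle, the parameter set used
#' throughout the package: inspired CO2 volume; inspiratory maximal
#' pressure and end-expiratory pressure (PEEP, mean patient pressure over
#' the final 50 ms of expiration); inspiratory and expiratory times and the
#' instantaneous breathing frequency 60/(Ti+Te); the time integrals of
#' patient-side pressure over each phase (cmH2O.s); patient- and
#' ventilator-side tidal volumes as trapezoidal integrals under the flow
#' curves; maximal flows per phase and side; and the invasive flag.
#'
#' Signs: patient-side tidal volumes are reported positive. Ventilator-side
#' flow is positive toward the patient, so `insp_vt_vent` is the gas
#' delivered from the ventilator during inspiration and `exp_vt_vent` the
#' net volume that moved *away* from the patient into the ventilator limb
#' during expiration - negative when the EPAP bias flow dominates the whole
#' expiration (no flow reversal).
#'
#' @param rec an aligned [recording()].
#' @param cycle one row of a `breath_cycles` table (list or data.frame row
#'   with `exp_start`, `insp_start`, `insp_end`).
#' @return A one-row data.frame with the 17 feature columns, or `NULL` if a
#'   phase is degenerate (< 2 samples).
#' @export
extract_features <- function(rec, cycle) {
  stopifnot(inherits(rec, "bipap_recording"))
  fs <- rec$sampling_rate; dt <- 1 / fs
  e0 <- cycle$exp_start; i0 <- cycle$insp_start; i1 <- cycle$insp_end
  n <- length(rec$channels$Q_pat)
  if (!(e0 < i0 && i0 < i1)) stop_invalid("cycle indices must be ordered")
  if (i1 > n || e0 < 1) stop_invalid("cycle outside recording bounds")
  if (i0 - e0 < 2 || i1 - i0 < 2) return(NULL)  # degenerate phase

  qp <- rec$channels$Q_pat; qv <- rec$channels$Q_vent
  pp <- rec$channels$P_pat; co2p <- rec$channels$CO2_pat

  exp_win <- e0:(i0 - 1L)   # half-open [exp_start, insp_start)
  insp_win <- i0:(i1 - 1L)

  ti <- (i1 - i0) / fs
  te <- (i0 - e0) / fs

  peep_k <- max(1L, as.integer(round(0.05 * fs)))
  peep_win <- max(e0, i0 - peep_k):(i0 - 1L)

  data.frame(
    insp_co2_volume = insp_co2_volume(qp, co2p, cycle, fs),
    insp_max_pressure_pat = max(pp[insp_win]),
    insp_time = ti,
    exp_time = te,
    insp_pressure_integral_pat = trapz_win(pp, i0, i1, dt),
    exp_pressure_integral_pat = trapz_win(pp, e0, i0, dt),
    insp_vt_pat = abs(trapz_win(qp, i0, i1, dt)),
    exp_vt_pat = abs(trapz_win(qp, e0, i0, dt)),
    insp_vt_vent = trapz_win(qv, i0, i1, dt),
    exp_vt_vent = -trapz_win(qv, e0, i0, dt),
    insp_max_flow_pat = max(abs(qp[insp_win])),
    exp_max_flow_pat = max(abs(qp[exp_win])),
    insp_max_flow_vent = max(abs(qv[insp_win])),
    exp_max_flow_vent = max(abs(qv[exp_win])),
    breath_frequency = 60 / (ti + te),
    peep = mean(pp[peep_win]),
    invasive = as.integer(rec$interface == "invasive"))
}

#' Inspired CO2 volume of one cycle
#'
#' Integral over the inspiration window of the CO2 flow curve - the
#' product of inspiratory (positive-clipped) patient-side airflow and the
#' CO2 concentration fraction - by the trapezoidal rule.
#'
#' @param flow patient-side flow series, ml/s.
#' @param co2_fraction patient-side CO2 series, %.
#' @param cycle cycle row with `insp_start`, `insp_end`.
#' @param fs sampling rate, Hz.
#' @return Inspired CO2 volume, ml.
#' @export
insp_co2_volume <- function(flow, co2_fraction, cycle, fs) {
  y <- pmax(flow, 0) * co2_fraction / 100
  trapz_win(y, cycle$insp_start, cycle$insp_end, 1 / fs)
}

#' Feature table for all cycles of a recording
#'
#' @param rec an aligned [recording()].
#' @param cycles a `breath_cycles` table from [segment_recording()].
#' @return data.frame, one row per non-degenerate cycle, with a leading
#'   `cycle` column and the 17 feature columns.
#' @export
extract_feature_table <- function(rec, cycles) {
  rows <- lapply(seq_len(nrow(cycles)), function(k) {
    f <- extract_features(rec, cycles[k, ])
    if (is.null(f)) return(NULL)
    cbind(cycle = cycles$cycle[k], f)
  })
  do.call(rbind, rows)
}

#' The 16 CO2-free predictor names
#'
#' All 17 per-cycle parameters except the inspired CO2 volume - the
#' variable set available to a ventilator that does not measure CO2, used
#' by both the discriminant analysis and the MLP classifier.
#'
#' @return Character vector of 16 column names.
#' @export
co2_free_predictors <- function() {
  c("insp_max_pressure_pat", "insp_time", "exp_time",
    "insp_pressure_integral_pat", "exp_pressure_integral_pat",
    "insp_vt_pat", "exp_vt_pat", "insp_vt_vent", "exp_vt_vent",
    "insp_max_flow_pat", "exp_max_flow_pat", "insp_max_flow_vent",
    "exp_max_flow_vent", "breath_frequency", "peep", "invasive")
}
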