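#' Labeler configuration
#'
#' Thresholds that operationalize "zero" and "positive" on the
#' ventilator-side CO2 curve. `zero_epsilon` is the level below which the
#' curve counts as zero; cycles whose inspiration-onset CO2 falls in
#' `(zero_epsilon, borderline_band]` are labelled borderline and excluded
#' from analysis, mirroring the elimination of cycles that cannot be
#' indisputably classified. The default borderline band (0.10 %CO2) aligns
#' the type III boundary with the significant-rebreathing level
#' (inspired CO2 fraction > 0.1%).
#'
#' @param zero_epsilon %CO2.
#' @param borderline_band %CO2, must exceed `zero_epsilon`.
#' @param fico2_threshold inspired CO2 fraction (%) above which rebreathing
#'   is flagged significant.
#' @param co2_smooth_window moving-average window (s) applied to the
#'   ventilator-side CO2 curve before thresholding. Raw capnometer noise is
#'   unbounded, so the maximum over a whole expiration would eventually
#'   exceed any fixed epsilon; a 50 ms average tames this while leaving
#'   the washout dynamics (time constants well above 0.1 s) intact. Set 0
#'   to threshold the raw samples.
#' @return An object of class `labeler_config`.
#' @export
labeler_config <- function(zero_epsilon = 0.05, borderline_band = 0.10,
                           fico2_threshold = 0.1, co2_smooth_window = 0.05) {
  if (!(zero_epsilon >= 0 && zero_epsilon < borderline_band))
    stop_invalid("need 0 <= zero_epsilon < borderline_band")
  if (fico2_threshold <= 0) stop_invalid("fico2_threshold must be > 0")
  if (co2_smooth_window < 0) stop_invalid("co2_smooth_window must be >= 0")
  structure(list(zero_epsilon = zero_epsilon,
                 borderline_band = borderline_band,
                 fico2_threshold = fico2_threshold,
                 co2_smooth_window = co2_smooth_window),
            class = "labeler_config")
}

#' Classify one cycle as type I, II, III or borderline
#'
#' Applies the reference (ventilator-side CO2) rules on an aligned
#' recording: type I if CO2 stays at zero (`<= zero_epsilon`) throughout
#' expiration; type II if it becomes positive during expiration but is
#' back at zero at the single inspiration-onset sample; type III if the
#' onset value exceeds `borderline_band`; onset values inside
#' `(zero_epsilon, borderline_band]` are borderline. Also detects the
#' type II/III flow-reversal signature on the ventilator-side flow and
#' flags significant rebreathing when the mean inspired CO2 fraction
#' (inspired CO2 volume / inspired volume) exceeds `fico2_threshold`.
#'
#' @param rec an aligned [recording()].
#' @param cycle a cycle row (`exp_start`, `insp_start`, `insp_end`).
#' @param config a [labeler_config()].
#' @return One-row data.frame: `type`, `vent_co2_at_insp_onset`,
#'   `max_vent_co2_during_exp`, `flow_reversal_detected`,
#'   `significant_rebreathing`.
#' @export
classify_cycle <- function(rec, cycle, config = labeler_config()) {
  stopifnot(inherits(rec, "bipap_recording"))
  fs <- rec$sampling_rate
  e0 <- cycle$exp_start; i0 <- cycle$insp_start; i1 <- cycle$insp_end
  n <- length(rec$channels$Q_pat)
  if (e0 < 1 || i1 > n || !(e0 < i0 && i0 < i1))
    stop_invalid("cycle outside recording")
  co2v <- rec$channels$CO2_vent
  if (config$co2_smooth_window > 0)
    co2v <- smooth_series(co2v, config$co2_smooth_window, fs)
  max_exp <- max(co2v[e0:(i0 - 1L)])
  onset <- co2v[i0]
  eps <- config$zero_epsilon; band <- config$borderline_band
  type <- if (max_exp <= eps) "I"
          else if (onset <= eps) "II"
          else if (onset > band) "III"
          else "borderline"
  rev <- detect_flow_reversal(rec, cycle)
  vco2 <- insp_co2_volume(rec$channels$Q_pat, rec$channels$CO2_pat, cycle, fs)
  vinsp <- abs(trapz_win(rec$channels$Q_pat, i0, i1, 1 / fs))
  fico2 <- if (vinsp > 0) 100 * vco2 / vinsp else 0
  data.frame(type = type, vent_co2_at_insp_onset = onset,
             max_vent_co2_during_exp = max_exp,
             flow_reversal_detected = rev$detected,
             significant_rebreathing = fico2 > config$fico2_threshold)
}

#' Detect mid-expiration reversal of ventilator-side flow
#'
#' In type II/III cycles the ventilator-side flow starts off directed away
#' from the patient (driven by the exhalation) and reverses toward the
#' patient when the decaying expiratory flow falls below the EPAP bias
#' flow. Reports whether the ventilator-side flow changes sign within the
#' expiration window (using a 10 ml/s hysteresis band against noise) and
#' the first sign-change sample.
#'
#' @param rec a [recording()].
#' @param cycle cycle row.
#' @param hysteresis ml/s.
#' @return list(`detected` logical, `sample` index or `NA`).
#' @export
detect_flow_reversal <- function(rec, cycle, hysteresis = 10) {
  qv <- rec$channels$Q_vent
  win <- cycle$exp_start:(cycle$insp_start - 1L)
  x <- qv[win]
  beyond <- which(abs(x) > hysteresis)
  if (length(beyond) < 2) return(list(detected = FALSE, sample = NA_integer_))
  sg <- sign(x[beyond])
  chg <- which(diff(sg) != 0)
  if (!length(chg)) return(list(detected = FALSE, sample = NA_integer_))
  conf <- beyond[chg[1] + 1]
  new <- sg[chg[1] + 1]
  i <- conf
  while (i > 1 && sign(x[i - 1]) == new) i <- i - 1
  list(detected = TRUE, sample = win[1] + i - 1L)
}

#' Label every cycle of a recording
#'
#' @param rec an aligned [recording()].
#' @param cycles a `breath_cycles` table.
#' @param config a [labeler_config()].
#' @param exclude integer vector of cycle ids to mark `excluded`
#'   (user-supplied artifact list).
#' @return data.frame, one row per cycle: `cycle`, `type`, onset/max CO2,
#'   flow-reversal and significant-rebreathing flags.
#' @export
label_cycles <- function(rec, cycles, config = labeler_config(),
                         exclude = integer()) {
  if (config$co2_smooth_window > 0) {  # smooth once, not per cycle
    rec$channels$CO2_vent <- smooth_series(rec$channels$CO2_vent,
                                           config$co2_smooth_window,
                                           rec$sampling_rate)
    config$co2_smooth_window <- 0
  }
  rows <- lapply(seq_len(nrow(cycles)), function(k) {
    lab <- classify_cycle(rec, cycles[k, ], config)
    cbind(cycle = cycles$cycle[k], lab)
  })
  out <- do.call(rbind, rows)
  out$type[out$cycle %in% exclude] <- "excluded"
  out
}

#' Composition summary of cycle labels
#'
#' Counts and percentages per type over analyzable (non-borderline,
#' non-excluded) cycles. Percentages are reported truncated to one decimal,
#' the convention under which shares are never overstated.
#'
#' @param labels data.frame with a `type` column, or a named vector of
#'   counts for types I/II/III.
#' @return data.frame: `type`, `count`, `percent`, plus an attribute
#'   `excluded` with the number of non-analyzable cycles.
#' @export
summarize_labels <- function(labels) {
  if (is.data.frame(labels)) {
    keep <- labels$type %in% c("I", "II", "III")
    excluded <- sum(!keep)
    counts <- table(factor(labels$type[keep], levels = c("I", "II", "III")))
  } else {
    if (is.null(names(labels))) names(labels) <- c("I", "II", "III")
    counts <- labels
    excluded <- 0L
  }
  total <- sum(counts)
  if (total < 1) stop_invalid("no analyzable cycles to summarize")
  pct <- floor(1000 * as.numeric(counts) / total) / 10
  out <- data.frame(type = names(counts), count = as.integer(counts),
                    percent = pct)
  attr(out, "excluded") <- excluded
  out
}
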