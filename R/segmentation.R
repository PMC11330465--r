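#' Segmentation configuration
#'
#' Zero-crossing detection on real flow signals needs noise robustness: a
#' crossing is accepted only once flow has moved beyond `hysteresis` on the
#' new side of zero, and phases shorter than `min_phase_duration` are
#' treated as artifacts (their two bounding crossings are dropped, merging
#' the blip into the surrounding phase). Defaults (10 ml/s, 0.2 s) are
#' chosen so adult breathing up to 60 breaths/min is never clipped while
#' typical flow-channel noise (SD ~5 ml/s) produces no spurious crossings.
#'
#' @param hysteresis ml/s.
#' @param min_phase_duration s.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(hysteresis = 10, min_phase_duration = 0.2) {
  if (hysteresis < 0) stop_invalid("hysteresis must be >= 0")
  if (min_phase_duration <= 0) stop_invalid("min_phase_duration must be > 0")
  structure(list(hysteresis = hysteresis,
                 min_phase_duration = min_phase_duration),
            class = "segmentation_config")
}

#' Detect flow zero-crossings
#'
#' Breath phase boundaries are the points where patient-side flow crosses
#' the zero line (inspiratory flow positive, expiratory negative). Each
#' reported crossing is the first sample past zero in the new direction; a
#' crossing is confirmed only after flow exceeds the hysteresis band on the
#' new side, and phases shorter than `min_phase_duration` are suppressed.
#'
#' @param flow numeric flow series, ml/s.
#' @param fs sampling rate, Hz.
#' @param config a [segmentation_config()].
#' @return data.frame with columns `sample` (1-based index) and `direction`
#'   (+1 for a crossing into inspiration, -1 into expiration), in time
#'   order with alternating directions. Never-crossing flow gives zero
#'   rows.
#' @export
detect_crossings <- function(flow, fs, config = segmentation_config()) {
  if (length(flow) < 2) stop_invalid("flow series must have length >= 2")
  h <- config$hysteresis
  # only excursions beyond the hysteresis band can confirm a crossing
  beyond <- which(abs(flow) > h)
  if (!length(beyond)) return(data.frame(sample = integer(), direction = integer()))
  sg <- sign(flow[beyond])
  chg <- which(diff(sg) != 0)  # confirmed direction changes
  samples <- integer(length(chg)); dirs <- integer(length(chg))
  sgn <- sign(flow)
  # a series starting inside the band starts at a phase boundary: report
  # the first sample past zero in the direction of the first excursion
  lead <- NULL
  if (abs(flow[1]) <= h) {
    i <- 1
    while (sgn[i] != sg[1]) i <- i + 1
    lead <- data.frame(sample = i, direction = sg[1])
  }
  for (j in seq_along(chg)) {
    conf <- beyond[chg[j] + 1]          # confirming sample in new direction
    old <- sg[chg[j]]; new <- sg[chg[j] + 1]
    # walk back to the last sample still strictly on the old side, then the
    # crossing is the first strictly-new-direction sample after it
    i <- conf
    while (i > 1 && sgn[i - 1] != old) i <- i - 1
    while (sgn[i] != new) i <- i + 1
    samples[j] <- i; dirs[j] <- new
  }
  if (!is.null(lead)) {
    samples <- c(lead$sample, samples); dirs <- c(lead$direction, dirs)
  }
  # suppress phases shorter than min_phase_duration by dropping both
  # bounding crossings (merges the short phase into its neighbours)
  min_len <- config$min_phase_duration * fs
  repeat {
    if (length(samples) < 2) break
    gaps <- diff(samples)
    bad <- which(gaps < min_len)
    if (!length(bad)) break
    drop <- c(bad[1], bad[1] + 1)
    samples <- samples[-drop]; dirs <- dirs[-drop]
  }
  data.frame(sample = samples, direction = dirs)
}

#' Assemble expiration-inspiration cycles from crossings
#'
#' The analysis unit is an expiration followed by the inspiration it
#' conditions: each crossing into expiration is paired with the subsequent
#' crossing into inspiration and the next crossing into expiration.
#' Phases are half-open `[start, end)`; consecutive cycles share boundary
#' samples. Leading/trailing partial phases are dropped.
#'
#' @param crossings data.frame from [detect_crossings()].
#' @param series_length total number of samples (bounds check).
#' @return data.frame of class `breath_cycles` with columns `cycle`,
#'   `exp_start`, `insp_start`, `insp_end` (sample indices) and `complete`.
#' @export
build_cycles <- function(crossings, series_length) {
  if (nrow(crossings) < 3)
    return(structure(data.frame(cycle = integer(), exp_start = integer(),
                                insp_start = integer(), insp_end = integer(),
                                complete = logical()),
                     class = c("breath_cycles", "data.frame")))
  if (any(diff(crossings$direction) == 0))
    stop_invalid("crossing directions must alternate")
  if (max(crossings$sample) > series_length)
    stop_invalid("crossing index beyond series length")
  down <- which(crossings$direction == -1)
  rows <- list()
  k <- 0L
  for (d in down) {
    if (d + 2 > nrow(crossings)) break
    k <- k + 1L
    rows[[k]] <- data.frame(cycle = k,
                            exp_start = crossings$sample[d],
                            insp_start = crossings$sample[d + 1],
                            insp_end = crossings$sample[d + 2],
                            complete = TRUE)
  }
  if (!k)
    return(structure(data.frame(cycle = integer(), exp_start = integer(),
                                insp_start = integer(), insp_end = integer(),
                                complete = logical()),
                     class = c("breath_cycles", "data.frame")))
  structure(do.call(rbind, rows), class = c("breath_cycles", "data.frame"))
}

#' Segment a recording into expiration-inspiration cycles
#'
#' Convenience wrapper: [detect_crossings()] on the patient-side flow, then
#' [build_cycles()].
#'
#' @param rec a [recording()].
#' @param config a [segmentation_config()].
#' @return A `breath_cycles` data.frame.
#' @export
segment_recording <- function(rec, config = segmentation_config()) {
  stopifnot(inherits(rec, "bipap_recording"))
  cr <- detect_crossings(rec$channels$Q_pat, rec$sampling_rate, config)
  build_cycles(cr, length(rec$channels$Q_pat))
}
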