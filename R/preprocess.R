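#' Undo the sidestream capnometer transport delay
#'
#' Sidestream capnometers aspirate gas through a sampling line, so the CO2
#' channels lag pressure and flow by `60 * line_volume / pump_flow`
#' seconds. This function advances (shifts earlier) `CO2_pat` and
#' `CO2_vent` by `round(delay * sampling_rate)` samples so all curves are
#' phased; the trailing gap is padded with the last value. The shift is
#' quantized to whole samples: the physical delay uncertainty exceeds one
#' sample, so sub-sample interpolation would add nothing.
#'
#' @param rec a [recording()].
#' @param delay delay in seconds; if `NULL` it is computed from
#'   `line_volume` and `pump_flow` with [compute_sampling_delay()].
#' @param line_volume,pump_flow sampling-line volume (ml) and pump flow
#'   (ml/min), used when `delay` is `NULL`.
#' @param smooth_window optional centered moving-average window (s) applied
#'   to the CO2 channels after alignment; 0 disables.
#' @return The recording with CO2 channels advanced; a provenance note is
#'   recorded in `rec$meta$alignment`.
#' @export
align_capnogram <- function(rec, delay = NULL, line_volume = NULL,
                            pump_flow = NULL, smooth_window = 0) {
  stopifnot(inherits(rec, "bipap_recording"))
  if (is.null(delay)) {
    if (is.null(line_volume) || is.null(pump_flow))
      stop_invalid("give either delay or (line_volume, pump_flow)")
    delay <- compute_sampling_delay(line_volume, pump_flow)
  }
  if (delay < 0) stop_invalid("delay must be >= 0")
  fs <- rec$sampling_rate
  n <- length(rec$channels[[1]])
  if (delay >= n / fs) stop_invalid("delay exceeds recording duration")
  shift <- as.integer(round(delay * fs))
  for (ch in c("CO2_pat", "CO2_vent")) {
    x <- rec$channels[[ch]]
    if (shift > 0) x <- c(x[(shift + 1):n], rep(x[n], shift))
    if (smooth_window > 0) x <- smooth_series(x, smooth_window, fs)
    rec$channels[[ch]] <- x
  }
  rec$meta$alignment <- list(delay_s = delay, shift_samples = shift,
                             smooth_window_s = smooth_window)
  rec
}

#' Centered moving-average smoothing
#'
#' Length-preserving moving average with boundary-value padding at the
#' edges; a window of 0 (or one spanning a single sample) is the identity.
#' Used to tame noise ahead of zero-crossing detection.
#'
#' @param x numeric series.
#' @param window window length in seconds.
#' @param fs sampling rate, Hz.
#' @return Smoothed series, same length as `x`.
#' @export
smooth_series <- function(x, window, fs) {
  if (window < 0) stop_invalid("window must be >= 0")
  k <- as.integer(round(window * fs))
  if (k %% 2 == 0) k <- k + 1L  # force odd so the window is centered
  if (window == 0 || k <= 1) return(x)
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  cs <- cumsum(c(0, xp))
  (cs[(k + 1):(length(xp) + 1)] - cs[1:(length(xp) - k + 1)]) / k
}
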