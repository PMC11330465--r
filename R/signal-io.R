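#' Multi-channel waveform recording container
#'
#' A recording holds synchronized sample series for the five mandatory
#' channel roles (`P_pat` patient-side pressure, cmH2O; `Q_pat`
#' patient-side flow, ml/s, inspiratory positive; `CO2_pat` patient-side
#' CO2 fraction, %; `Q_vent` ventilator-side flow, ml/s, positive toward
#' the patient; `CO2_vent` ventilator-side CO2 fraction, %) and optionally
#' `O2_pat` (%). Samples are treated as uniformly spaced at
#' `sampling_rate`.
#'
#' @param channels named list of equal-length numeric vectors.
#' @param sampling_rate Hz.
#' @param interface `"invasive"` or `"noninvasive"`.
#' @param subject_id opaque identifier.
#' @param time_origin time of the first sample, s.
#' @param meta free-form metadata list (provenance notes etc.).
#' @return An object of class `bipap_recording`.
#' @export
recording <- function(channels, sampling_rate,
                      interface = c("invasive", "noninvasive"),
                      subject_id = "anon", time_origin = 0, meta = list()) {
  interface <- match.arg(interface)
  rec <- structure(list(channels = channels, sampling_rate = sampling_rate,
                        interface = interface, subject_id = subject_id,
                        time_origin = time_origin, meta = meta),
                   class = "bipap_recording")
  validate_recording(rec)
  rec
}

mandatory_roles <- c("P_pat", "Q_pat", "CO2_pat", "Q_vent", "CO2_vent")
channel_units <- c(P_pat = "cmH2O", Q_pat = "ml/s", CO2_pat = "%",
                   Q_vent = "ml/s", CO2_vent = "%", O2_pat = "%")

validate_recording <- function(rec) {
  if (!length(rec$channels)) stop_invalid("recording has no channels")
  missing <- setdiff(mandatory_roles, names(rec$channels))
  if (length(missing))
    stop_invalid("missing mandatory channel(s): ",
                 paste(missing, collapse = ", "))
  lens <- vapply(rec$channels, length, integer(1))
  if (length(unique(lens)) != 1)
    stop_invalid("channel series must all have equal length")
  if (!is.numeric(rec$sampling_rate) || rec$sampling_rate <= 0)
    stop_invalid("sampling_rate must be > 0")
  for (ch in intersect(c("CO2_pat", "CO2_vent"), names(rec$channels))) {
    x <- rec$channels[[ch]]
    if (any(!is.finite(x)) || min(x) < -1e-9 || max(x) > 15)
      stop_invalid(ch, " must lie in [0, 15] %")
  }
  invisible(rec)
}

#' @export
print.bipap_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("BiPAP recording '%s' (%s): %d samples @ %g Hz (%.1f s), channels: %s\n",
              x$subject_id, x$interface, n, x$sampling_rate,
              n / x$sampling_rate, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path, ignore.case = TRUE)

#' Read a waveform recording from CSV + JSON sidecar
#'
#' The CSV must contain a `time_s` column plus one column per channel role;
#' the JSON sidecar carries `sampling_rate`, per-channel `units`,
#' `interface` and `subject_id`. Canonical units are cmH2O for pressure,
#' ml/s for flow and % for gas fractions; flow given as "L/min" is
#' converted (x 1000/60). CO2 in mmHg is not accepted. The time column is
#' used only to validate uniform spacing (1 ppm tolerance).
#'
#' @param path path to the CSV file (sidecar expected at the same path with
#'   extension `.json`).
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(path)) stop_invalid("no such file: ", path)
  if (!file.exists(sc_path)) stop_invalid("missing JSON sidecar: ", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (is.null(sc$sampling_rate) || sc$sampling_rate <= 0)
    stop_invalid("sidecar must declare a positive sampling_rate")
  df <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop_invalid("CSV must have a time_s column")
  roles <- setdiff(names(df), "time_s")
  missing <- setdiff(mandatory_roles, roles)
  if (length(missing))
    stop_invalid("missing mandatory channel(s): ",
                 paste(missing, collapse = ", "))
  fs <- sc$sampling_rate
  if (nrow(df) > 2) {
    steps <- diff(df$time_s)
    if (max(abs(steps - 1 / fs)) > (1 / fs) * 1e-6 + 1e-12)
      stop_invalid("irregular time step (beyond 1 ppm of 1/sampling_rate)")
  }
  units <- sc$units
  channels <- list()
  for (r in roles) {
    x <- df[[r]]
    u <- if (!is.null(units)) units[[r]] %||% channel_units[[r]] else channel_units[[r]]
    canon <- channel_units[[r]]
    if (identical(u, canon)) {
      # no conversion
    } else if (identical(u, "L/min") && canon == "ml/s") {
      x <- x * 1000 / 60
    } else if (identical(u, "mmHg")) {
      stop_invalid("CO2 in mmHg is not supported for channel ", r)
    } else {
      stop_invalid("unit '", u, "' for channel ", r,
                   " is neither canonical ('", canon,
                   "') nor a declared conversion")
    }
    channels[[r]] <- x
  }
  recording(channels, sampling_rate = fs,
            interface = sc$interface %||% "invasive",
            subject_id = sc$subject_id %||% "anon",
            time_origin = sc$time_origin %||% df$time_s[1],
            meta = as.list(sc$meta %||% list()))
}

#' Write a recording to CSV + JSON sidecar
#'
#' Numeric values are formatted with `%.9g`, which round-trips the signals
#' within float precision; all metadata goes to the sidecar so the CSV
#' stays purely numeric.
#'
#' @param rec a [recording()].
#' @param path destination CSV path; the sidecar is written next to it.
#' @return Invisibly, the two file paths.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  n <- length(rec$channels[[1]])
  fs <- rec$sampling_rate
  cols <- c(list(time_s = rec$time_origin + (seq_len(n) - 1) / fs),
            rec$channels)
  txt <- vapply(cols, function(x) sprintf("%.9g", x), character(n))
  if (n == 1) txt <- matrix(txt, nrow = 1, dimnames = list(NULL, names(cols)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(cols), collapse = ","), con)
  writeLines(apply(txt, 1, paste, collapse = ","), con)
  sc <- list(sampling_rate = fs,
             units = as.list(channel_units[names(rec$channels)]),
             interface = rec$interface, subject_id = rec$subject_id,
             time_origin = rec$time_origin, meta = rec$meta)
  jsonlite::write_json(sc, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(csv = path, sidecar = sidecar_path(path)))
}

#' Write / read per-cycle ground-truth tables
#'
#' Plain-CSV persistence for the simulator's truth table (cycle index,
#' type, rebreathed volume, boundary samples) and for feature/label tables.
#'
#' @param truth data.frame as in [simulate_recording()]'s `truth` element.
#' @param path CSV path.
#' @return `write_truth` invisibly returns `path`; `read_truth` returns the
#'   data.frame.
#' @export
write_truth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) read.csv(path, stringsAsFactors = FALSE)
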