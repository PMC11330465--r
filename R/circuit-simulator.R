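#' Circuit configuration for the leak-circuit simulator
#'
#' Describes the ventilator, the intentional leak and the gas-sampling line.
#' The leak port is modelled as a linear conductance (leak flow =
#' `leak_conductance * pressure`); an orifice square-root law would also be
#' plausible, but the linear law keeps the bias flow and the flow-reversal
#' condition analytically transparent.
#'
#' @param epap,ipap expiratory / inspiratory positive airway pressure, cmH2O.
#' @param leak_conductance leak flow per unit pressure, ml/s per cmH2O.
#' @param vent_limb_volume internal volume of the modelled ventilator-side
#'   limb, ml.
#' @param vent_limb_cells number of well-mixed cells discretising the
#'   ventilator limb (plug-flow advection between cells).
#' @param pat_limb_volume apparatus dead space between the leak port and the
#'   patient, ml.
#' @param sample_line_volume internal volume of the sidestream sampling
#'   line, ml.
#' @param pump_flow capnometer aspiration flow, ml/min.
#' @param capnometer_smoothing_tau first-order smoothing time constant of
#'   the capnometer, s (0 disables smoothing).
#' @return An object of class `circuit_config`.
#' @export
circuit_config <- function(epap = 4, ipap = 14, leak_conductance = 90,
                           vent_limb_volume = 500, vent_limb_cells = 20,
                           pat_limb_volume = 60, sample_line_volume = 4.0,
                           pump_flow = 150, capnometer_smoothing_tau = 0.05) {
  if (!(ipap > epap && epap > 0))
    stop_invalid("need ipap > epap > 0 (got ipap=", ipap, ", epap=", epap, ")")
  if (leak_conductance <= 0) stop_invalid("leak_conductance must be > 0")
  if (vent_limb_cells < 1) stop_invalid("vent_limb_cells must be >= 1")
  if (vent_limb_volume < 0 || pat_limb_volume < 0 || sample_line_volume < 0)
    stop_invalid("volumes must be >= 0")
  if (pump_flow <= 0) stop_invalid("pump_flow must be > 0")
  structure(list(epap = epap, ipap = ipap,
                 leak_conductance = leak_conductance,
                 vent_limb_volume = vent_limb_volume,
                 vent_limb_cells = as.integer(vent_limb_cells),
                 pat_limb_volume = pat_limb_volume,
                 sample_line_volume = sample_line_volume,
                 pump_flow = pump_flow,
                 capnometer_smoothing_tau = capnometer_smoothing_tau),
            class = "circuit_config")
}

#' Patient (breathing-pattern) configuration for the simulator
#'
#' The simulated patient is a prescribed flow source: a half-sine
#' inspiration delivering `tidal_volume` over the inspiratory time, and a
#' passive exponential expiration with time constant `exp_flow_tau` whose
#' integral matches the inspired volume. Expired gas CO2 follows a rising
#' exponential capnogram towards `fetco2`.
#'
#' @param respiratory_rate breaths per minute.
#' @param ti_fraction inspiratory fraction of the cycle, in (0, 1).
#' @param tidal_volume ml.
#' @param fetco2 end-tidal CO2 plateau, % (0 to 15).
#' @param exp_flow_tau expiratory flow decay constant, s.
#' @param capnogram_tau rise time constant of the expired CO2 front, s.
#' @param cycle_jitter_cv coefficient of variation of per-cycle log-normal
#'   timing jitter (0 = perfectly regular).
#' @param noise_sd named list of additive Gaussian noise SDs per channel
#'   class: `pressure` (cmH2O), `flow` (ml/s), `co2` (%CO2).
#' @param seed integer seed for jitter and noise.
#' @return An object of class `patient_config`.
#' @export
patient_config <- function(respiratory_rate = 20, ti_fraction = 0.4,
                           tidal_volume = 500, fetco2 = 5,
                           exp_flow_tau = 0.4, capnogram_tau = 0.15,
                           cycle_jitter_cv = 0.03,
                           noise_sd = list(pressure = 0.2, flow = 5,
                                           co2 = 0.02),
                           seed = 1L) {
  if (respiratory_rate <= 0) stop_invalid("respiratory_rate must be > 0")
  if (ti_fraction <= 0 || ti_fraction >= 1)
    stop_invalid("ti_fraction must be in (0, 1)")
  if (fetco2 < 0 || fetco2 > 15) stop_invalid("fetco2 must be in [0, 15]")
  if (tidal_volume < 0) stop_invalid("tidal_volume must be >= 0")
  if (exp_flow_tau <= 0 || capnogram_tau <= 0)
    stop_invalid("time constants must be > 0")
  nd <- list(pressure = 0.2, flow = 5, co2 = 0.02)
  nd[names(noise_sd)] <- noise_sd
  structure(list(respiratory_rate = respiratory_rate,
                 ti_fraction = ti_fraction, tidal_volume = tidal_volume,
                 fetco2 = fetco2, exp_flow_tau = exp_flow_tau,
                 capnogram_tau = capnogram_tau,
                 cycle_jitter_cv = cycle_jitter_cv,
                 noise_sd = nd, seed = as.integer(seed)),
            class = "patient_config")
}

#' Transport delay of a sidestream gas-sampling line
#'
#' A sidestream capnometer aspirates gas through a sampling line; the
#' concentration reading lags the circuit by the time the gas takes to
#' transit the line: `delay = 60 * line_volume / pump_flow`.
#'
#' @param line_volume internal volume of the sampling line, ml.
#' @param pump_flow aspiration flow, ml/min.
#' @return Delay in seconds.
#' @examples
#' compute_sampling_delay(4.0, 150)  # 1.6 s
#' compute_sampling_delay(4.0, 100)  # 2.4 s
#' @export
compute_sampling_delay <- function(line_volume, pump_flow) {
  if (line_volume < 0) stop_invalid("line_volume must be >= 0")
  if (pump_flow <= 0) stop_invalid("pump_flow must be > 0")
  60 * line_volume / pump_flow
}

# Build the deterministic phase schedule: alternating insp/exp phases
# starting with an inspiration, with optional log-normal duration jitter.
# Returns a data.frame(phase, t0, t1) covering at least `duration`.
phase_schedule <- function(patient, duration) {
  t_cycle <- 60 / patient$respiratory_rate
  ti <- patient$ti_fraction * t_cycle
  te <- t_cycle - ti
  cv <- patient$cycle_jitter_cv
  sdl <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  phases <- list(); t <- 0; k <- 0
  while (t < duration) {
    m <- if (sdl > 0) rlnorm(1, meanlog = -sdl^2 / 2, sdlog = sdl) else 1
    phases[[k + 1]] <- c(t, t + ti * m, t + ti * m + te * m)
    t <- t + (ti + te) * m
    k <- k + 1
  }
  ph <- do.call(rbind, phases)
  data.frame(insp_start = ph[, 1], exp_start = ph[, 2], cycle_end = ph[, 3])
}

#' Simulate a BiPAP leak-circuit recording with per-cycle ground truth
#'
#' Generates synchronized pressure, flow and CO2 waveforms on both sides of
#' the leak port by integrating CO2 advection through a discretized circuit
#' (see [circuit_config()]), then optionally applies the sidestream
#' capnometer forward model ([apply_capnometer()]) and additive channel
#' noise. Each expiration-inspiration cycle is labelled from the noiseless
#' ventilator-side CO2 state: type I if CO2 never enters the ventilator
#' limb during expiration, type II if it enters but the port-adjacent cell
#' is back at zero by inspiration onset, type III otherwise. The true
#' rebreathed CO2 volume is the CO2 advected from the ventilator limb
#' across the port toward the patient during the following inspiration; it
#' is exactly 0 for types I and II.
#'
#' @param patient a [patient_config()].
#' @param circuit a [circuit_config()].
#' @param duration recording length, s (must cover at least 2 full cycles).
#' @param sampling_rate Hz.
#' @param interface `"invasive"` or `"noninvasive"`.
#' @param capnometer if `TRUE`, CO2 channels are delayed and smoothed as a
#'   sidestream capnometer would report them (undo with
#'   [align_capnogram()]).
#' @param subject_id opaque identifier stored in the recording.
#' @return An object of class `simulated_recording`: a list with elements
#'   `recording` (a [recording()]) and `truth` (a data.frame with one row
#'   per complete expiration-inspiration cycle: `cycle`, `type`,
#'   `rebreathed_ml`, `exp_start`, `insp_start`, `insp_end` sample indices)
#'   plus a `balance` data.frame of cumulative CO2 bookkeeping terms.
#' @export
simulate_recording <- function(patient, circuit, duration = 60,
                               sampling_rate = 200,
                               interface = c("invasive", "noninvasive"),
                               capnometer = TRUE,
                               subject_id = "sim") {
  stopifnot(inherits(patient, "patient_config"),
            inherits(circuit, "circuit_config"))
  interface <- match.arg(interface)
  if (circuit$leak_conductance * circuit$epap <= 0)
    stop_invalid("leak flow at EPAP is zero: circuit cannot vent")
  if (duration < 2 * 60 / patient$respiratory_rate)
    stop_invalid("duration must cover at least 2 full cycles")
  fs <- sampling_rate
  dt <- 1 / fs
  n <- as.integer(round(duration * fs))

  set.seed(patient$seed)
  sched <- phase_schedule(patient, duration)

  tt <- (seq_len(n) - 1) * dt
  q_pat <- numeric(n)      # + toward patient (inspiration positive)
  c_src <- numeric(n)      # expired-gas CO2 at the patient end, %
  p_target <- numeric(n)
  insp_idx <- pmin(n, as.integer(round(sched$insp_start * fs)) + 1L)
  exp_idx <- pmin(n, as.integer(round(sched$exp_start * fs)) + 1L)
  end_idx <- pmin(n, as.integer(round(sched$cycle_end * fs)) + 1L)

  for (k in seq_len(nrow(sched))) {
    ti <- sched$exp_start[k] - sched$insp_start[k]
    te <- sched$cycle_end[k] - sched$exp_start[k]
    i0 <- insp_idx[k]; i1 <- min(exp_idx[k] - 1L, n); i2 <- min(end_idx[k] - 1L, n)
    if (i0 > n) break
    # inspiration: half-sine delivering tidal_volume over ti
    ts <- tt[i0:i1] - sched$insp_start[k]
    q_pat[i0:i1] <- patient$tidal_volume * pi / (2 * ti) * sin(pi * ts / ti)
    p_target[i0:i1] <- circuit$ipap
    if (i1 + 1L > n) break
    # expiration: exponential decay, integral matched to tidal_volume
    ts <- tt[(i1 + 1L):i2] - sched$exp_start[k]
    amp <- patient$tidal_volume /
      (patient$exp_flow_tau * (1 - exp(-te / patient$exp_flow_tau)))
    q_pat[(i1 + 1L):i2] <- -amp * exp(-ts / patient$exp_flow_tau)
    c_src[(i1 + 1L):i2] <- patient$fetco2 *
      (1 - exp(-ts / patient$capnogram_tau))
    p_target[(i1 + 1L):i2] <- circuit$epap
  }
  if (end_idx[nrow(sched)] <= n)
    p_target[end_idx[nrow(sched)]:n] <- circuit$epap

  # pressure-source dynamics: first-order approach to the set level
  tau_p <- 0.08
  a <- exp(-dt / tau_p)
  pressure <- as.numeric(filter((1 - a) * p_target, a, method = "recursive",
                                init = p_target[1]))

  core <- .advect_core(q_pat, c_src, pressure, circuit$leak_conductance,
                       circuit$vent_limb_cells, circuit$vent_limb_volume,
                       max(1L, as.integer(round(circuit$pat_limb_volume / 15))),
                       circuit$pat_limb_volume, dt)

  # ---- ground truth per expiration-inspiration cycle ----
  eps_truth <- 1e-3  # %CO2: numerical zero for the noiseless vent-side cell
  truth <- NULL
  nk <- nrow(sched)
  rows <- list()
  cyc <- 0L
  for (k in seq_len(nk - 1L)) {
    e0 <- exp_idx[k]              # expiration start (sample)
    i0 <- insp_idx[k + 1L]        # following inspiration start
    i1 <- exp_idx[k + 1L]         # its end
    if (i1 > n || i0 > n) break
    cyc <- cyc + 1L
    max_exp <- max(core$co2_vent[e0:(i0 - 1L)])
    onset <- core$co2_vent[i0]
    rebr <- core$rebreathed[i1 - 1L] - core$rebreathed[i0 - 1L]
    type <- if (max_exp <= eps_truth) "I"
            else if (onset <= eps_truth) "II" else "III"
    if (type != "III") rebr <- 0
    rows[[cyc]] <- data.frame(cycle = cyc, type = type,
                              rebreathed_ml = rebr, exp_start = e0,
                              insp_start = i0, insp_end = i1)
  }
  truth <- do.call(rbind, rows)

  channels <- list(P_pat = pressure, Q_pat = q_pat,
                   CO2_pat = pmax(0, core$co2_pat),  # clip float roundoff
                   Q_vent = core$q_vent,
                   CO2_vent = pmax(0, core$co2_vent))
  rec <- recording(channels, sampling_rate = fs, interface = interface,
                   subject_id = subject_id)
  if (capnometer) rec <- apply_capnometer(rec, circuit)

  nd <- patient$noise_sd
  if (any(unlist(nd) > 0)) {
    rec$channels$P_pat <- rec$channels$P_pat + rnorm(n, 0, nd$pressure)
    rec$channels$Q_pat <- rec$channels$Q_pat + rnorm(n, 0, nd$flow)
    rec$channels$Q_vent <- rec$channels$Q_vent + rnorm(n, 0, nd$flow)
    rec$channels$CO2_pat <- pmax(0, rec$channels$CO2_pat +
                                   rnorm(n, 0, nd$co2))
    rec$channels$CO2_vent <- pmax(0, rec$channels$CO2_vent +
                                    rnorm(n, 0, nd$co2))
  }

  balance <- data.frame(exhaled = core$exhaled, leak_out = core$leak_out,
                        vent_end_out = core$vent_end_out,
                        reinhaled = core$reinhaled,
                        rebreathed = core$rebreathed,
                        content = core$content)
  structure(list(recording = rec, truth = truth, balance = balance,
                 patient = patient, circuit = circuit),
            class = "simulated_recording")
}

#' @export
print.simulated_recording <- function(x, ...) {
  cat("Simulated leak-circuit recording:",
      length(x$recording$channels$Q_pat), "samples at",
      x$recording$sampling_rate, "Hz\n")
  if (!is.null(x$truth)) print(table(cycle_type = x$truth$type))
  invisible(x)
}

#' Sidestream capnometer forward model
#'
#' Delays the CO2 channels by the sampling-line transport delay
#' (`60 * sample_line_volume / pump_flow`, quantized to whole samples,
#' leading samples padded with the first value) and optionally applies
#' first-order smoothing with time constant `capnometer_smoothing_tau`.
#' Pressure and flow channels are untouched. This is the forward model that
#' [align_capnogram()] undoes.
#'
#' @param rec a [recording()].
#' @param circuit a [circuit_config()].
#' @return The recording with transformed CO2 channels.
#' @export
apply_capnometer <- function(rec, circuit) {
  stopifnot(inherits(rec, "bipap_recording"))
  fs <- rec$sampling_rate
  shift <- as.integer(round(
    compute_sampling_delay(circuit$sample_line_volume, circuit$pump_flow) * fs))
  tau <- circuit$capnometer_smoothing_tau
  for (ch in c("CO2_pat", "CO2_vent")) {
    x <- rec$channels[[ch]]
    if (is.null(x)) stop_invalid("CO2 channel ", ch, " missing")
    if (shift > 0)
      x <- c(rep(x[1], shift), x[seq_len(length(x) - shift)])
    if (tau > 0) {
      a <- exp(-1 / (fs * tau))
      x <- as.numeric(filter(x * (1 - a), a, method = "recursive",
                             init = x[1]))
    }
    rec$channels[[ch]] <- x
  }
  rec$meta$capnometer <- list(delay_samples = shift, smoothing_tau = tau)
  rec
}

#' Per-type means and SDs of the 17 cycle parameters
#'
#' Reference class statistics (mean and SD of each of the 17 per-cycle
#' respiratory parameters, per cycle type, plus per-type sample sizes and
#' invasive-ventilation proportions) as observed in adult ICU BiPAP
#' recordings. Used to parameterize [sample_feature_table()].
#'
#' @return An object of class `class_stats`: list with matrices `mean` and
#'   `sd` (rows = parameters, columns = types I/II/III), vector `n`, vector
#'   `p_invasive`.
#' @export
cycle_type_class_stats <- function() {
  par_names <- c("insp_co2_volume", "insp_max_pressure_pat", "insp_time",
                 "exp_time", "insp_pressure_integral_pat",
                 "exp_pressure_integral_pat", "insp_vt_pat", "exp_vt_pat",
                 "insp_vt_vent", "exp_vt_vent", "insp_max_flow_pat",
                 "exp_max_flow_pat", "insp_max_flow_vent",
                 "exp_max_flow_vent", "breath_frequency", "peep")
  m <- rbind(
    insp_co2_volume            = c(0.48, 0.39, 4.92),
    insp_max_pressure_pat      = c(24,   26.3, 14.4),
    insp_time                  = c(1.0,  1.1,  1.2),
    exp_time                   = c(1.2,  1.7,  1.5),
    insp_pressure_integral_pat = c(16.4, 22.6, 12.6),
    exp_pressure_integral_pat  = c(12,   17.4, 9.7),
    insp_vt_pat                = c(394,  590,  610),
    exp_vt_pat                 = c(252,  537,  594),
    insp_vt_vent               = c(825,  1141, 1027),
    exp_vt_vent                = c(-69,  81.5, 307),
    insp_max_flow_pat          = c(683,  799,  703),
    exp_max_flow_pat           = c(385,  617,  575),
    insp_max_flow_vent         = c(1215, 1394, 1108),
    exp_max_flow_vent          = c(106,  341,  387),
    breath_frequency           = c(31,   24,   25),
    peep                       = c(10.1, 10.4, 6.6))
  s <- rbind(
    insp_co2_volume            = c(0.25, 0.31, 4.88),
    insp_max_pressure_pat      = c(5.4,  4.6,  3.5),
    insp_time                  = c(0.8,  0.4,  0.5),
    exp_time                   = c(0.5,  0.7,  0.6),
    insp_pressure_integral_pat = c(7.9,  6.5,  5.3),
    exp_pressure_integral_pat  = c(5,    7,    3.9),
    insp_vt_pat                = c(238,  200,  283),
    exp_vt_pat                 = c(87,   165,  270),
    insp_vt_vent               = c(472,  347,  435),
    exp_vt_vent                = c(83.6, 94.7, 191),
    insp_max_flow_pat          = c(223,  114,  116),
    exp_max_flow_pat           = c(106,  99,   81),
    insp_max_flow_vent         = c(296,  171,  137),
    exp_max_flow_vent          = c(76,   91,   84),
    breath_frequency           = c(8.2,  8,    6.1),
    peep                       = c(1.4,  1.3,  0.3))
  colnames(m) <- colnames(s) <- c("I", "II", "III")
  stopifnot(identical(rownames(m), par_names))
  structure(list(mean = m, sd = s,
                 n = c(I = 1849L, II = 1545L, III = 1353L),
                 p_invasive = c(I = 1196 / 1849, II = 1026 / 1545,
                                III = 1002 / 1353),
                 correlation = NULL),
            class = "class_stats")
}

#' Draw a labelled per-cycle feature table from class statistics
#'
#' Samples per-class feature vectors from a multivariate normal with the
#' class means/SDs of `stats` (independent normals if no correlation matrix
#' is supplied). Features that are nonnegative by definition (all except
#' `exp_vt_vent`) are censored at 0; because plain censoring inflates the
#' mean of strongly skewed features, the normal's location is first shifted
#' so that the censored draw reproduces the class mean exactly
#' (mean-preserving zero-censoring). The `invasive` flag is Bernoulli with
#' the per-class probability.
#'
#' @param stats a `class_stats` object, e.g. [cycle_type_class_stats()].
#' @param n_per_class integer vector (length 1 or one per class).
#' @param seed integer seed.
#' @return data.frame with the 17 feature columns plus `cycle_type`
#'   (factor I/II/III).
#' @export
sample_feature_table <- function(stats = cycle_type_class_stats(),
                                 n_per_class, seed = 1L) {
  stopifnot(inherits(stats, "class_stats"))
  classes <- colnames(stats$mean)
  if (length(n_per_class) == 1) n_per_class <- rep(n_per_class, length(classes))
  if (any(n_per_class < 1)) stop_invalid("n_per_class must be >= 1")
  p <- nrow(stats$mean)
  R <- stats$correlation
  L <- NULL
  if (!is.null(R)) {
    if (!isSymmetric(unname(R)) || min(eigen(R, symmetric = TRUE,
                                             only.values = TRUE)$values) < -1e-8)
      stop_invalid("correlation matrix must be symmetric positive semi-definite")
    ev <- eigen(R, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  }
  set.seed(as.integer(seed))
  out <- vector("list", length(classes))
  neg_ok <- "exp_vt_vent"
  # location m such that E[max(0, N(m, s))] = mu (mean-preserving censoring)
  censor_location <- function(mu, s) {
    if (s == 0 || mu / s > 6) return(mu)
    f <- function(m) m * stats::pnorm(m / s) + s * stats::dnorm(m / s) - mu
    stats::uniroot(f, c(mu - 6 * s, mu), tol = 1e-10)$root
  }
  for (j in seq_along(classes)) {
    nk <- n_per_class[j]
    Z <- matrix(rnorm(nk * p), nk, p)
    if (!is.null(L)) Z <- Z %*% t(L)
    mu_j <- stats$mean[, j]
    adj <- mu_j
    for (i in seq_len(p))
      if (!(rownames(stats$mean)[i] %in% neg_ok))
        adj[i] <- censor_location(mu_j[i], stats$sd[i, j])
    X <- sweep(sweep(Z, 2, stats$sd[, j], `*`), 2, adj, `+`)
    colnames(X) <- rownames(stats$mean)
    X <- as.data.frame(X)
    for (cn in setdiff(colnames(X), neg_ok)) X[[cn]] <- pmax(0, X[[cn]])
    X$invasive <- rbinom(nk, 1, stats$p_invasive[j])
    X$cycle_type <- classes[j]
    out[[j]] <- X
  }
  res <- do.call(rbind, out)
  res$cycle_type <- factor(res$cycle_type, levels = classes)
  rownames(res) <- NULL
  res
}
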