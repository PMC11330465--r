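# shared fixtures: small noiseless / noisy simulations reused across tests

no_noise <- list(pressure = 0, flow = 0, co2 = 0)

# breathing patterns that reliably generate each cycle type
sim_type_I <- function(duration = 40, noise = FALSE, seed = 1L, ...) {
  simulate_recording(
    patient_config(respiratory_rate = 12, tidal_volume = 300,
                   exp_flow_tau = 0.5, cycle_jitter_cv = 0,
                   noise_sd = if (noise) list(pressure = 0.2, flow = 5,
                                              co2 = 0.02) else no_noise,
                   seed = seed),
    circuit_config(leak_conductance = 160),
    duration = duration, ...)
}

sim_type_II <- function(duration = 40, noise = FALSE, seed = 1L, ...) {
  simulate_recording(
    patient_config(respiratory_rate = 15, tidal_volume = 450,
                   exp_flow_tau = 0.4, cycle_jitter_cv = 0,
                   noise_sd = if (noise) list(pressure = 0.2, flow = 5,
                                              co2 = 0.02) else no_noise,
                   seed = seed),
    circuit_config(leak_conductance = 90),
    duration = duration, ...)
}

sim_type_III <- function(duration = 40, noise = FALSE, seed = 1L, ...) {
  simulate_recording(
    patient_config(respiratory_rate = 30, tidal_volume = 700,
                   exp_flow_tau = 0.35, cycle_jitter_cv = 0,
                   noise_sd = if (noise) list(pressure = 0.2, flow = 5,
                                              co2 = 0.02) else no_noise,
                   seed = seed),
    circuit_config(leak_conductance = 40),
    duration = duration, ...)
}

# apply the rule labeler at the simulator's true boundaries
truth_labels_by_rules <- function(sim, config = labeler_config()) {
  vapply(seq_len(nrow(sim$truth)), function(k)
    classify_cycle(sim$recording, sim$truth[k, ], config)$type,
    character(1))
}

# per-cycle CO2 bookkeeping from the cumulative balance table
cycle_balance <- function(sim) {
  b <- sim$balance; tr <- sim$truth
  t(vapply(seq_len(nrow(tr)), function(k) {
    i0 <- tr$exp_start[k]; i1 <- tr$insp_end[k]
    d <- function(col) b[[col]][i1] - b[[col]][i0]
    c(exhaled = d("exhaled"),
      out = d("leak_out") + d("vent_end_out") + d("reinhaled"),
      dcontent = b$content[i1] - b$content[i0])
  }, numeric(3)))
}
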