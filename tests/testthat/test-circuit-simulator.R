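test_that("sampling-line transport delay follows volume / pump-flow", {
  expect_equal(compute_sampling_delay(4.0, 150), 1.6)
  expect_equal(compute_sampling_delay(4.0, 100), 2.4)
  expect_equal(compute_sampling_delay(0.0, 100), 0.0)
  expect_error(compute_sampling_delay(4.0, 0), "pump_flow")
  expect_error(compute_sampling_delay(4.0, -5), "pump_flow")
})

test_that("config invariants are enforced", {
  expect_error(circuit_config(epap = 10, ipap = 8), "ipap > epap")
  expect_error(circuit_config(leak_conductance = 0), "leak_conductance")
  expect_error(patient_config(ti_fraction = 1.2), "ti_fraction")
  expect_error(patient_config(fetco2 = 20), "fetco2")
})

test_that("without a CO2 source every cycle is type I and channels are zero", {
  sim <- simulate_recording(
    patient_config(fetco2 = 0, cycle_jitter_cv = 0, noise_sd = no_noise),
    circuit_config(), duration = 20, capnometer = FALSE)
  expect_true(all(sim$truth$type == "I"))
  expect_true(all(sim$truth$rebreathed_ml == 0))
  expect_equal(max(abs(sim$recording$channels$CO2_pat)), 0)
  expect_equal(max(abs(sim$recording$channels$CO2_vent)), 0)
})

test_that("gentle breathing against a large leak gives pure type I cycles", {
  sim <- sim_type_I(capnometer = FALSE)
  expect_gt(nrow(sim$truth), 2)
  expect_true(all(sim$truth$type == "I"))
  # rule labeler on the noiseless channels agrees with truth on every cycle
  expect_true(all(truth_labels_by_rules(sim) == sim$truth$type))
})

test_that("fast large-VT breathing against a small leak rebreathes (type III)", {
  sim <- sim_type_III(capnometer = FALSE)
  expect_true(any(sim$truth$type == "III"))
  iii <- sim$truth[sim$truth$type == "III", ]
  expect_true(all(iii$rebreathed_ml > 0))
  # vent-side CO2 is still positive at the truth inspiration onset
  expect_true(all(sim$recording$channels$CO2_vent[iii$insp_start] > 0.1))
  expect_true(all(truth_labels_by_rules(sim) == sim$truth$type))
})

test_that("intermediate pattern washes CO2 out before inspiration (type II)", {
  sim <- sim_type_II(capnometer = FALSE)
  expect_true(all(sim$truth$type == "II"))
  expect_true(all(sim$truth$rebreathed_ml == 0))
  # CO2 did enter the ventilator limb during expiration
  for (k in seq_len(nrow(sim$truth))) {
    win <- sim$truth$exp_start[k]:(sim$truth$insp_start[k] - 1)
    expect_gt(max(sim$recording$channels$CO2_vent[win]), 0.5)
  }
})

test_that("per-cycle CO2 mass balance closes to within 1%", {
  for (sim in list(sim_type_II(capnometer = FALSE),
                   sim_type_III(capnometer = FALSE))) {
    cb <- cycle_balance(sim)
    rel <- abs(cb[, "exhaled"] - cb[, "out"] - cb[, "dcontent"]) /
      cb[, "exhaled"]
    expect_lt(max(rel), 0.01)
  }
})

test_that("type III cycles never revert to type I under rebreathing-promoting changes", {
  base <- list(rate = 24, vt = 550, leak = 60)
  mk <- function(rate, vt, leak)
    simulate_recording(
      patient_config(respiratory_rate = rate, tidal_volume = vt,
                     exp_flow_tau = 0.35, cycle_jitter_cv = 0,
                     noise_sd = no_noise),
      circuit_config(leak_conductance = leak),
      duration = 30, capnometer = FALSE)$truth$type
  t0 <- mk(base$rate, base$vt, base$leak)
  expect_true(any(t0 == "III"))
  # higher rate, higher VT, smaller leak: each should keep (or worsen) III
  for (types in list(mk(base$rate + 6, base$vt, base$leak),
                     mk(base$rate, base$vt + 150, base$leak),
                     mk(base$rate, base$vt, base$leak - 20))) {
    expect_gte(mean(types == "III"), mean(t0 == "III") - 1e-9)
    expect_false(any(types == "I"))
  }
})

test_that("same seed and configuration reproduce the recording bit for bit", {
  a <- sim_type_II(duration = 20, noise = TRUE, seed = 42)
  b <- sim_type_II(duration = 20, noise = TRUE, seed = 42)
  expect_identical(a$recording$channels, b$recording$channels)
  expect_identical(a$truth, b$truth)
})

test_that("capnometer forward model shifts and smooths only CO2 channels", {
  sim <- sim_type_II(duration = 20, capnometer = FALSE)
  rec <- sim$recording
  # delay 0, tau 0: identity
  c0 <- circuit_config(sample_line_volume = 0, capnometer_smoothing_tau = 0)
  expect_equal(apply_capnometer(rec, c0)$channels, rec$channels)
  # delay 1.6 s at 200 Hz: pure 320-sample shift with leading-value padding
  c1 <- circuit_config(sample_line_volume = 4, pump_flow = 150,
                       capnometer_smoothing_tau = 0)
  out <- apply_capnometer(rec, c1)
  n <- length(rec$channels$CO2_pat)
  expect_equal(out$channels$CO2_pat,
               c(rep(rec$channels$CO2_pat[1], 320),
                 rec$channels$CO2_pat[seq_len(n - 320)]))
  expect_identical(out$channels$Q_pat, rec$channels$Q_pat)
  expect_identical(out$channels$P_pat, rec$channels$P_pat)
  # smoothing is a low-pass: never exceeds the input maximum
  c2 <- circuit_config(sample_line_volume = 0, capnometer_smoothing_tau = 0.2)
  sm <- apply_capnometer(rec, c2)
  expect_lte(max(sm$channels$CO2_vent), max(rec$channels$CO2_vent) + 1e-12)
})

test_that("feature-table sampler honors the class statistics", {
  cs <- cycle_type_class_stats()
  # degenerate SDs: every row equals its class mean
  cs0 <- cs
  cs0$sd[] <- 0
  ft <- sample_feature_table(cs0, n_per_class = 5, seed = 1)
  for (cl in c("I", "II", "III")) {
    sub <- ft[ft$cycle_type == cl, rownames(cs$mean)]
    expect_equal(unname(as.matrix(sub)),
                 matrix(cs0$mean[, cl], 5, 16, byrow = TRUE))
  }
  # published class mean of type III inspired CO2 volume is reproduced
  ft <- sample_feature_table(cs, n_per_class = 10000, seed = 2)
  m <- mean(ft$insp_co2_volume[ft$cycle_type == "III"])
  se <- 4.88 / sqrt(10000)
  expect_lt(abs(m - 4.92), 3 * se)
  # nonnegativity contract (exp_vt_vent may be negative)
  nonneg <- setdiff(rownames(cs$mean), "exp_vt_vent")
  expect_true(all(as.matrix(ft[, nonneg]) >= 0))
  expect_true(any(ft$exp_vt_vent < 0))
  # determinism
  expect_identical(sample_feature_table(cs, 50, seed = 9),
                   sample_feature_table(cs, 50, seed = 9))
  # invalid correlation matrix
  csr <- cs
  csr$correlation <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(sample_feature_table(csr, 5, seed = 1), "semi-definite")
})
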