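# build a recording directly from channel pieces (no segmentation involved)
channels_rec <- function(n, fs = 100, interface = "invasive", ...) {
  ch <- list(P_pat = rep(0, n), Q_pat = rep(0, n), CO2_pat = rep(0, n),
             Q_vent = rep(0, n), CO2_vent = rep(0, n))
  mod <- list(...)
  ch[names(mod)] <- mod
  recording(ch, sampling_rate = fs, interface = interface)
}

test_that("integral features match closed forms on simple pulses", {
  fs <- 100
  # cycle: expiration samples 1..101, inspiration 101..201
  cyc <- list(exp_start = 1L, insp_start = 101L, insp_end = 201L)

  # rectangular inspiratory flow 500 ml/s for 1.0 s, CO2 1% throughout
  qp <- rep(0, 220); qp[101:220] <- 500
  rec <- channels_rec(220, fs, Q_pat = qp, CO2_pat = rep(1, 220))
  f <- extract_features(rec, cyc)
  expect_equal(f$insp_vt_pat, 500, tolerance = 1e-9)
  expect_equal(f$insp_max_flow_pat, 500, tolerance = 1e-9)
  # CO2 flow integral: 500 ml/s x 1% x 1 s = 5 ml
  expect_equal(f$insp_co2_volume, 5, tolerance = 1e-9)
  expect_equal(f$insp_time, 1.0)
  expect_equal(f$exp_time, 1.0)
  expect_equal(f$breath_frequency, 30)
  expect_equal(f$invasive, 1L)

  # triangular pressure pulse 0 -> 20 -> 0 cmH2O across the 1 s inspiration
  pp <- rep(0, 220)
  pp[101:201] <- 20 * (1 - abs(seq(-1, 1, length.out = 101)))
  rec <- channels_rec(220, fs, P_pat = pp, Q_pat = qp)
  f <- extract_features(rec, cyc)
  expect_equal(f$insp_pressure_integral_pat, 10, tolerance = 1e-9)
  expect_equal(f$insp_max_pressure_pat, 20, tolerance = 1e-9)

  # triangular expiratory flow 0 -> -800 -> 0 over the 1 s expiration
  qe <- rep(0, 220); qe[1:101] <- -800 * (1 - abs(seq(-1, 1, length.out = 101)))
  rec <- channels_rec(220, fs, Q_pat = qe)
  f <- extract_features(rec, cyc)
  expect_equal(f$exp_vt_pat, 400, tolerance = 1e-9)
  expect_equal(f$exp_max_flow_pat, 800, tolerance = 1e-9)

  # constant expiratory pressure: PEEP is the end-expiratory mean
  pe <- rep(0, 220); pe[1:100] <- 5
  rec <- channels_rec(220, fs, P_pat = pe, Q_pat = qp)
  f <- extract_features(rec, cyc)
  expect_equal(f$peep, 5, tolerance = 1e-9)

  # ventilator-side signs: bias flow toward patient all expiration gives a
  # negative exp_vt_vent
  qv <- rep(0, 220); qv[1:100] <- 300; qv[101:220] <- 1000
  rec <- channels_rec(220, fs, Q_vent = qv, Q_pat = qp)
  f <- extract_features(rec, cyc)
  expect_lt(f$exp_vt_vent, 0)
  expect_equal(f$insp_vt_vent, 1000, tolerance = 1e-2)
  expect_equal(f$insp_max_flow_vent, 1000)

  # degenerate phase: no features
  expect_null(extract_features(rec, list(exp_start = 1L, insp_start = 2L,
                                         insp_end = 3L)))
  expect_error(extract_features(rec, list(exp_start = 10L, insp_start = 5L,
                                          insp_end = 20L)), "ordered")
})

test_that("zero CO2 gives zero inspired CO2 volume", {
  cyc <- list(exp_start = 1L, insp_start = 50L, insp_end = 120L)
  expect_equal(insp_co2_volume(rep(400, 150), rep(0, 150), cyc, 100), 0)
})

test_that("features agree with a 10x refined-grid oracle within 1%", {
  pat <- patient_config(respiratory_rate = 15, tidal_volume = 450,
                        exp_flow_tau = 0.4, cycle_jitter_cv = 0,
                        noise_sd = no_noise)
  cir <- circuit_config(leak_conductance = 90)
  fine <- simulate_recording(pat, cir, duration = 20, sampling_rate = 2000,
                             capnometer = FALSE)
  coarse <- simulate_recording(pat, cir, duration = 20, sampling_rate = 200,
                               capnometer = FALSE)
  k <- 3L  # a mid-recording cycle
  tr_f <- fine$truth[k, ]; tr_c <- coarse$truth[k, ]
  # boundaries describe the same instants
  expect_equal((tr_f$insp_start - 1) / 2000, (tr_c$insp_start - 1) / 200,
               tolerance = 1e-9)
  f <- extract_features(coarse$recording, tr_c)
  # independent dense-grid integration (plain Riemann sums at 2000 Hz)
  dense_int <- function(x, i0, i1) sum(x[i0:(i1 - 1)]) / 2000
  ch <- fine$recording$channels
  o_insp_vt <- abs(dense_int(ch$Q_pat, tr_f$insp_start, tr_f$insp_end))
  o_exp_vt <- abs(dense_int(ch$Q_pat, tr_f$exp_start, tr_f$insp_start))
  o_ivv <- dense_int(ch$Q_vent, tr_f$insp_start, tr_f$insp_end)
  o_evv <- -dense_int(ch$Q_vent, tr_f$exp_start, tr_f$insp_start)
  o_pins <- dense_int(ch$P_pat, tr_f$insp_start, tr_f$insp_end)
  o_co2 <- sum(pmax(ch$Q_pat[tr_f$insp_start:(tr_f$insp_end - 1)], 0) *
                 ch$CO2_pat[tr_f$insp_start:(tr_f$insp_end - 1)] / 100) / 2000
  rel <- function(a, b) abs(a - b) / max(abs(b), 1e-6)
  expect_lt(rel(f$insp_vt_pat, o_insp_vt), 0.01)
  expect_lt(rel(f$exp_vt_pat, o_exp_vt), 0.01)
  expect_lt(rel(f$insp_vt_vent, o_ivv), 0.01)
  expect_lt(rel(f$exp_vt_vent, o_evv), 0.01)
  expect_lt(rel(f$insp_pressure_integral_pat, o_pins), 0.01)
  expect_lt(rel(f$insp_co2_volume, o_co2), 0.05)
})

test_that("patient-side tidal volumes balance on leak-symmetric cycles", {
  sim <- sim_type_II(duration = 30, capnometer = FALSE)
  ft <- extract_feature_table(sim$recording, sim$truth)
  expect_true(all(abs(ft$insp_vt_pat - ft$exp_vt_pat) < 0.01 * 450))
})

test_that("inspired CO2 volume of type III cycles tracks true rebreathing", {
  sim <- sim_type_III(duration = 40, capnometer = FALSE)
  iii <- sim$truth[sim$truth$type == "III", ]
  ft <- extract_feature_table(sim$recording, iii)
  # measured at the port-side sensor: equals CO2 advected across the port
  expect_true(all(abs(ft$insp_co2_volume - iii$rebreathed_ml) <
                    0.10 * pmax(iii$rebreathed_ml, 1)))
})
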