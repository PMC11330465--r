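test_that("flat ventilator-side CO2 is type I", {
  n <- 400
  rec <- recording(list(P_pat = rep(4, n), Q_pat = c(rep(-300, 200),
                                                     rep(300, 200)),
                        CO2_pat = rep(0, n), Q_vent = rep(300, n),
                        CO2_vent = rep(0, n)), sampling_rate = 100)
  lab <- classify_cycle(rec, list(exp_start = 1L, insp_start = 201L,
                                  insp_end = 400L))
  expect_equal(lab$type, "I")
  expect_false(lab$flow_reversal_detected)
  expect_false(lab$significant_rebreathing)
})

test_that("constructed flow reversal is found at the sign change", {
  n <- 400
  qv <- c(rep(-200, 100), rep(100, 300))
  rec <- recording(list(P_pat = rep(4, n), Q_pat = c(rep(-300, 200),
                                                     rep(300, 200)),
                        CO2_pat = rep(0, n), Q_vent = qv,
                        CO2_vent = rep(0, n)), sampling_rate = 100)
  cyc <- list(exp_start = 1L, insp_start = 201L, insp_end = 400L)
  rev <- detect_flow_reversal(rec, cyc)
  expect_true(rev$detected)
  expect_lte(abs(rev$sample - 101L), 1L)
  # constant-direction ventilator flow: no reversal
  rec$channels$Q_vent <- rep(250, n)
  expect_false(detect_flow_reversal(rec, cyc)$detected)
})

test_that("labeler reproduces simulator truth and rebreathing flags", {
  # type II: CO2 enters the limb, is flushed, and the flow reverses
  sim2 <- sim_type_II(capnometer = FALSE)
  lab2 <- label_cycles(sim2$recording, sim2$truth)
  expect_true(all(lab2$type == "II"))
  expect_true(all(lab2$flow_reversal_detected))
  expect_true(all(!lab2$significant_rebreathing))
  # type III: positive CO2 at onset, significant inspired CO2 fraction
  sim3 <- sim_type_III(capnometer = FALSE)
  lab3 <- label_cycles(sim3$recording, sim3$truth)
  expect_true(all(lab3$type == sim3$truth$type))
  iii <- lab3$type == "III"
  expect_true(all(lab3$flow_reversal_detected[iii]))
  expect_true(all(lab3$vent_co2_at_insp_onset[iii] > 0.1))
  # ~7.6 ml rebreathed in ~700 ml inspired: FICO2 > 0.1% by a wide margin
  expect_true(all(lab3$significant_rebreathing[iii]))
})

test_that("the labeler survives realistic noise after alignment", {
  sim <- sim_type_I(duration = 60, noise = TRUE, seed = 21)
  rec <- align_capnogram(sim$recording, line_volume = 4, pump_flow = 150)
  lab <- label_cycles(rec, sim$truth)
  ok <- lab$type != "borderline"
  expect_gte(mean(lab$type[ok] == sim$truth$type[ok]), 0.99)
})

test_that("labels partition analyzable cycles and are monotone in epsilon", {
  sim <- sim_type_III(capnometer = FALSE)
  lab <- label_cycles(sim$recording, sim$truth)
  expect_true(all(lab$type %in% c("I", "II", "III", "borderline")))
  # raising zero_epsilon never turns type I into II/III
  cfg_lo <- labeler_config(zero_epsilon = 0.02, borderline_band = 0.1)
  cfg_hi <- labeler_config(zero_epsilon = 0.09, borderline_band = 0.1)
  simI <- sim_type_I(noise = TRUE, capnometer = FALSE, seed = 2)
  lab_lo <- label_cycles(simI$recording, simI$truth, cfg_lo)
  lab_hi <- label_cycles(simI$recording, simI$truth, cfg_hi)
  was_I <- lab_lo$type == "I"
  expect_true(all(lab_hi$type[was_I] == "I"))
})

test_that("composition summary reproduces printed study percentages", {
  s <- summarize_labels(c(I = 1849, II = 1545, III = 1353))
  expect_equal(s$percent, c(38.9, 32.5, 28.5))
  expect_equal(sum(s$count), 4747)
  expect_equal(summarize_labels(c(I = 10, II = 0, III = 0))$percent,
               c(100, 0, 0))
  expect_equal(summarize_labels(c(I = 1, II = 1, III = 1))$percent,
               rep(33.3, 3))
  # borderline/excluded cycles are counted but not in the percentages
  df <- data.frame(type = c(rep("I", 3), "borderline", "excluded"))
  s2 <- summarize_labels(df)
  expect_equal(attr(s2, "excluded"), 2L)
  expect_equal(s2$percent, c(100, 0, 0))
  expect_error(summarize_labels(data.frame(type = "borderline")), "analyzable")
})
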