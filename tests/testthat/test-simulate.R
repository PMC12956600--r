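test_that("the same seed reproduces a test bit for bit", {
  prof <- zero_noise_child_profile()
  p <- child_participant(); pr <- child_protocol()
  a <- simulate_test(prof, p, pr, seed = 10)
  b <- simulate_test(prof, p, pr, seed = 10)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # with noise and jitter on, different seeds give different breaths
  noisy <- physio_profile(vo2_rest = 6 * 32.3, oues_a = 950,
                          vo2peak_rel = 45.4, ouep = 39.6)
  na <- simulate_test(noisy, p, pr, seed = 10)
  nb <- simulate_test(noisy, p, pr, seed = 10)
  nc <- simulate_test(noisy, p, pr, seed = 11)
  expect_identical(as.data.frame(na), as.data.frame(nb))
  expect_false(identical(as.data.frame(na), as.data.frame(nc)))
})

test_that("zero-noise construction inverts to the planted OUES exactly", {
  prof <- zero_noise_child_profile()
  s <- simulate_test(prof, child_participant(), child_protocol(), seed = 1)
  fit <- compute_oues(s, body_mass = 32.3)
  tr <- ground_truth(s)
  expect_lt(abs(fit$oues_a / prof$oues_a - 1), 1e-6)
  expect_lt(abs(fit$oues_b / tr$oues_b - 1), 1e-6)
})

test_that("zero-noise OUEP sits within 1% of the planted VO2/VE maximum", {
  s <- simulate_test(zero_noise_child_profile(), child_participant(),
                     child_protocol(), seed = 1)
  tr <- ground_truth(s)
  ouep <- compute_ouep(moving_average(s, 30))
  expect_lt(abs(as.numeric(ouep) / tr$ouep_pointwise_max - 1), 0.01)
})

test_that("zero-noise thresholds are recovered at the planted times", {
  s <- simulate_test(zero_noise_child_profile(), child_participant(),
                     child_protocol(), seed = 1)
  tr <- ground_truth(s)
  vt1 <- detect_vt(s, "VT1", 32.3)
  vt2 <- detect_vt(s, "VT2", 32.3)
  expect_true(vt1$found); expect_true(vt2$found)
  # VT1 hinge is exact piecewise-linear: recovered to grid resolution
  expect_lt(abs(vt1$t - tr$t_vt1), 2)
  # VT2 sits on the RER-divided equivalent, a gently curved baseline:
  # recovered within a few breaths
  expect_lt(abs(vt2$t - tr$t_vt2), 10)
  expect_lt(abs(vt2$vo2_rel - tr$vo2_vt2_rel), 0.5)
  # PetCO2 cross-check marks the same transition
  expect_lt(abs(vt2$cross_t - tr$t_vt2), 10)
})

test_that("planted plateaus are detected and non-plateaus are not", {
  p <- child_participant(); pr <- child_protocol()
  s0 <- simulate_test(zero_noise_child_profile(FALSE), p, pr, seed = 2)
  s1 <- simulate_test(zero_noise_child_profile(TRUE, 0.3), p, pr, seed = 2)
  d0 <- detect_plateau(moving_average(s0, 30), pr)
  d1 <- detect_plateau(moving_average(s1, 30), pr)
  expect_false(d0$plateau)
  expect_true(d1$plateau)
  expect_equal(d1$observed_rise / d1$expected_rise, 0.3, tolerance = 0.1)
})

test_that("impossible profiles are rejected", {
  p <- child_participant()
  pr <- ramp_protocol(50, 30)
  low <- physio_profile(vo2_rest = 300, vo2peak_rel = 20, oues_a = 900,
                        ouep = 40)
  # 20 mL/kg/min * 32.3 kg = 646 mL/min < warm-up demand at 50 W
  expect_error(simulate_test(low, p, pr, seed = 1), "warm-up demand")
  expect_error(physio_profile(vt1_frac = 0.9, vt2_frac = 0.8), "vt1_frac")
  expect_error(physio_profile(plateau = TRUE, plateau_fraction = 0.6),
               "plateau_fraction")
})

test_that("a default children cohort is well-formed and QC-clean", {
  co <- generate_cohort(group_spec("children"), n = 18, seed = 21)
  expect_length(co, 18L)
  expect_true(all(vapply(co, function(el) qc_screen(el$series)$usable,
                         logical(1))))
  durations <- vapply(co, function(el) {
    ph <- phases(el$series); (ph$termination - ph$ramp_start) / 60
  }, numeric(1))
  expect_true(all(durations >= 6 & durations <= 12))
})

test_that("cohorts are bit-identical under the same seed and extensible", {
  a <- generate_cohort(group_spec("MTA"), n = 6, seed = 33)
  b <- generate_cohort(group_spec("MTA"), n = 6, seed = 33)
  expect_identical(lapply(a, function(el) as.data.frame(el$series)),
                   lapply(b, function(el) as.data.frame(el$series)))
  # counter-based sub-seeds: the first participants of a larger cohort match
  big <- generate_cohort(group_spec("MTA"), n = 8, seed = 33)
  expect_identical(as.data.frame(a[[3]]$series),
                   as.data.frame(big[[3]]$series))
})

test_that("planted cohort means obey the law of large numbers", {
  co <- generate_cohort(group_spec("children"), n = 200, seed = 8)
  planted <- vapply(co, function(el) el$profile$vo2peak_rel, numeric(1))
  se <- 6.6 / sqrt(200)
  expect_lt(abs(mean(planted) - 45.4), 2 * se)
})

test_that("raising planted peak VO2 never lowers the pipeline peak", {
  p <- child_participant(); pr <- child_protocol()
  peaks <- vapply(seq(38, 54, by = 2), function(v) {
    prof <- physio_profile(
      vo2_rest = 6 * 32.3, oues_a = 950, vo2peak_rel = v, ouep = 39.6,
      vt1_frac = 0.6, vt2_frac = 0.9, hr_max = 197, hr_rest = 85,
      rer_max = 1.06,
      noise_sd = c(vo2 = 0, vco2 = 0, ve = 0, hr = 0, peto2 = 0, petco2 = 0),
      jitter_sd = 0)
    s <- simulate_test(prof, p, pr, seed = 5)
    compute_vo2peak(moving_average(s, 30), 32.3)$vo2peak_rel
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})

test_that("default-noise cohorts recover OUES and VT2 to stated precision", {
  errs_oues <- c(); errs_vt2 <- c()
  for (g in c("children", "MTA", "WTA")) {
    co <- generate_cohort(group_spec(g), seed = 55)
    for (el in co) {
      sm <- moving_average(el$series, 30)
      tr <- ground_truth(el$series)
      fit <- compute_oues(sm, body_mass = el$participant$body_mass)
      errs_oues <- c(errs_oues, fit$oues_a / tr$oues_a - 1)
      vt2 <- detect_vt(sm, "VT2", el$participant$body_mass)
      if (vt2$found) errs_vt2 <- c(errs_vt2, vt2$vo2_rel - tr$vo2_vt2_rel)
    }
  }
  expect_gt(length(errs_oues), 50)
  expect_lt(abs(mean(errs_oues)), 0.02)            # OUES bias < 2%
  expect_lt(sqrt(mean(errs_vt2^2)), 3)             # VT2 RMSE < 3 mL/kg/min
  expect_gt(length(errs_vt2) / length(errs_oues), 0.9)
})
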