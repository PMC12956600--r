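test_that("peak VO2 is the smoothed-channel maximum", {
  t <- seq(0, 300, by = 2)
  s <- toy_series(t, vo2 = 400 + 3 * t, hr = 100 + 0.2 * t)
  sm <- moving_average(s, 30)
  pk <- compute_vo2peak(sm, body_mass = 30)
  expect_equal(pk$vo2peak_abs, max(sm$vo2) / 1000)       # brute-force max
  expect_equal(pk$t_peak, 300)                            # monotone: last breath
  expect_equal(pk$vo2peak_rel, max(sm$vo2) / 30)
  expect_equal(pk$hr_max, max(sm$hr))
  short <- toy_series(c(0, 5, 20), c(500, 510, 520))
  expect_error(compute_vo2peak(short, 30), "smoothing window")
})

test_that("plateau boundary at exactly 50% of the expected rise is not a plateau", {
  pr <- ramp_protocol(20, 15)                 # expected rise 150 mL/min
  t <- seq(0, 600, by = 1)
  mk <- function(slope) {                     # linear VO2, uniform 1-s breaths
    toy_series(t, vo2 = 800 + slope * t, ramp_start = 0, termination = 600)
  }
  exact_half <- detect_plateau(mk(75 / 60), pr)     # rise 75 = 0.5 * 150
  expect_false(exact_half$plateau)                  # strict "<"
  expect_equal(exact_half$observed_rise, 75, tolerance = 1e-9)
  below <- detect_plateau(mk(74 / 60), pr)
  expect_true(below$plateau)
  full <- detect_plateau(mk(150 / 60), pr)          # 100% of expected
  expect_false(full$plateau)
  flat <- detect_plateau(mk(0), pr)                 # 0% of expected
  expect_true(flat$plateau)
})

test_that("scaling the final-minute rise down can never clear a plateau", {
  pr <- ramp_protocol(20, 15)
  t <- seq(0, 600, by = 1)
  verdicts <- vapply(seq(1, 0, by = -0.1), function(scale) {
    vo2 <- 800 + 2.5 * pmin(t, 540) + scale * 2.5 * pmax(t - 540, 0)
    detect_plateau(toy_series(t, vo2, ramp_start = 0, termination = 600),
                   pr)$plateau
  }, logical(1))
  expect_true(all(diff(as.integer(verdicts)) >= 0))  # FALSE -> TRUE only
})

test_that("a short ramp yields a not-evaluable plateau result, not an error", {
  pr <- ramp_protocol(20, 15)
  t <- seq(0, 100, by = 1)
  res <- detect_plateau(toy_series(t, 800 + t, ramp_start = 0,
                                   termination = 100), pr)
  expect_false(res$evaluable)
  expect_true(is.na(res$plateau))
})

test_that("exhaustion thresholds are closed at the printed boundaries", {
  mk <- function(rer = NA, hr = NA) list(rer_max = rer, hr_max = hr)
  expect_true(check_exhaustion(mk(rer = 1.13), "MTA"))        # inclusive >=
  expect_false(check_exhaustion(mk(rer = 1.1299), "WTA"))
  expect_false(check_exhaustion(mk(rer = 1.00), "MTA"))
  expect_true(check_exhaustion(mk(hr = 186), "children"))     # 0.95*195 = 185.25
  expect_false(check_exhaustion(mk(hr = 185), "children"))
  expect_true(check_exhaustion(mk(hr = 185.25), "children"))
  expect_error(check_exhaustion(mk(rer = 1.2), "children"), "hr")
  expect_error(check_exhaustion(mk(hr = 190), "MTA"), "rer")
})

test_that("OUE is VO2/VE with scale invariance", {
  s <- toy_series(c(0, 10, 20), vo2 = c(2000, 2000, 2000),
                  ve = c(50, 50, 50))
  expect_equal(compute_oue(s), c(40, 40, 40))
  s2 <- toy_series(c(0, 10, 20), vo2 = 2 * c(2000, 2000, 2000),
                   ve = 2 * c(50, 50, 50))
  expect_equal(compute_oue(s2), compute_oue(s))
  set.seed(1)
  t <- sort(runif(50, 0, 100))
  vo2 <- runif(50, 500, 2500); ve <- runif(50, 10, 80)
  expect_equal(compute_oue(toy_series(t, vo2, ve = ve)), vo2 / ve)
})

test_that("OUEP equals the exhaustive window oracle and dominates every window", {
  expect_equal(as.numeric(compute_ouep(
    toy_series(seq(0, 200, 2), vo2 = rep(2000, 101), ve = rep(50, 101)))), 40)

  set.seed(3)
  t <- sort(runif(400, 0, 600))
  vo2 <- 800 + 2 * t + rnorm(400, 0, 60)
  ve <- (vo2 / 1000) * (25 + 0.02 * t)
  s <- toy_series(t, vo2, ve = ve)
  got <- compute_ouep(s)
  g <- resample_to_grid(s, dt = 1)
  oue <- g$vo2 / g$ve
  windows <- vapply(seq_len(length(oue) - 90), function(i) {
    mean(oue[i:(i + 90)])      # brute force over every 1-s offset
  }, numeric(1))
  expect_equal(as.numeric(got), max(windows), tolerance = 1e-12)
  expect_true(all(as.numeric(got) >= windows - 1e-12))

  short <- toy_series(c(0, 30, 60), c(500, 510, 520))
  expect_true(is.na(compute_ouep(short)))
  expect_false(attr(compute_ouep(short), "evaluable"))
})

test_that("OUES reproduces an exact log-linear relation and the OLS oracle", {
  ve <- seq(8, 90, length.out = 60)
  s <- toy_series(seq_along(ve), vo2 = 1500 * log10(ve) + 300, ve = ve)
  fit <- compute_oues(s, body_mass = 50)
  expect_equal(fit$oues_a, 1500, tolerance = 1e-9)
  expect_equal(fit$oues_b, 300, tolerance = 1e-9)
  expect_equal(fit$oues_rel, 30, tolerance = 1e-9)

  set.seed(11)
  ve <- runif(200, 5, 120)
  vo2 <- 1200 * log10(ve) + 500 + rnorm(200, 0, 80)
  s2 <- toy_series(seq_along(ve), vo2 = vo2, ve = ve)
  fit2 <- compute_oues(s2)
  want <- ols_oracle(log10(ve), vo2)
  expect_equal(fit2$oues_b, want[1], tolerance = 1e-9)
  expect_equal(fit2$oues_a, want[2], tolerance = 1e-9)
  # normal equations hold: residuals orthogonal to the regressor
  resid <- vo2 - fit2$oues_a * log10(ve) - fit2$oues_b
  expect_lt(abs(sum(resid)) / sum(abs(vo2)), 1e-12)
  expect_lt(abs(sum(resid * log10(ve))) / sum(abs(vo2)), 1e-12)

  expect_error(compute_oues(toy_series(1:20, vo2 = 1:20 * 100,
                                       ve = rep(30, 20))), "singular")
})

test_that("OUES is invariant under breath-time reparameterisation", {
  set.seed(2)
  ve <- runif(100, 10, 90)
  vo2 <- 1000 * log10(ve) + 400 + rnorm(100, 0, 50)
  a <- compute_oues(toy_series(seq_along(ve), vo2, ve = ve))
  b <- compute_oues(toy_series(sqrt(seq_along(ve)) * 10, vo2, ve = ve))
  expect_equal(a$oues_a, b$oues_a)
})

test_that("O2-per-watt matches the oracle, scales linearly, and needs a ramp", {
  t <- seq(0, 480, by = 2)
  power <- 20 + pmax(t - 120, 0) * 15 / 60
  vo2 <- 300 + 10 * power
  s <- breath_series(
    data.frame(t = t, vo2 = vo2, vco2 = 0.9 * vo2, ve = vo2 / 40,
               hr = NA, peto2 = NA, petco2 = NA, power = power),
    list(warmup_start = 0, ramp_start = 120, termination = 480))
  got <- compute_o2_per_watt(s)
  keep <- t >= 135 & t <= 465    # ramp minus the 15-s trim
  want <- ols_oracle(power[keep], vo2[keep])[2]
  expect_equal(got, want, tolerance = 1e-9)
  expect_equal(got, 10, tolerance = 1e-9)

  s2 <- s; s2$vo2 <- 2 * s2$vo2
  expect_equal(compute_o2_per_watt(s2), 2 * got, tolerance = 1e-9)

  flat <- toy_series(t, vo2, power = rep(50, length(t)))
  expect_error(compute_o2_per_watt(flat), "constant power")
})

test_that("simulated O2-per-watt sits near the 10 mL/min/W gain", {
  s <- simulate_test(zero_noise_child_profile(), child_participant(),
                     child_protocol(), seed = 6)
  o2w <- compute_o2_per_watt(moving_average(s, 30))
  expect_equal(o2w, 10, tolerance = 0.05)   # first-order lag costs < 5%
})
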