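# Shared builders for the test suite. Everything is generated in code; no
# binary fixtures.

# A zero-noise child profile whose planted values sit at the cohort means.
zero_noise_child_profile <- function(plateau = FALSE, plateau_fraction = 0.3) {
  physio_profile(
    vo2_rest = 6 * 32.3, oues_a = 29.5 * 32.3, vo2peak_rel = 45.4,
    ouep = 39.6, vt1_frac = 0.603, vt2_frac = 41.5 / 45.4,
    hr_max = 197, hr_rest = 85, rer_max = 1.06,
    plateau = plateau, plateau_fraction = plateau_fraction,
    noise_sd = c(vo2 = 0, vco2 = 0, ve = 0, hr = 0, peto2 = 0, petco2 = 0),
    jitter_sd = 0)
}

child_participant <- function(id = "c01") {
  participant(id, "children", "female", 9.5, 32.3, 139)
}

child_protocol <- function() select_ramp_protocol(45.4 * 32.3 / 10)

# A hand-buildable breath series: supply t and channel vectors; defaults
# give a valid, boring test.
toy_series <- function(t, vo2, ve = rep(30, length(t)),
                       vco2 = 0.9 * vo2, power = rep(50, length(t)),
                       hr = NA_real_, ramp_start = 0,
                       termination = max(t) + 1) {
  breath_series(
    data.frame(t = t, vo2 = vo2, vco2 = vco2, ve = ve, hr = hr,
               peto2 = NA_real_, petco2 = NA_real_, power = power),
    list(warmup_start = 0, ramp_start = ramp_start,
         termination = termination))
}

# Independent OLS oracle by explicit normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}

# Independent breakpoint oracle: the documented two-stage search, coded
# with lm() formulas. Stage one scans every candidate split on [lo, hi] of
# the grid with a sharp hinge; stage two rescans a +/-60 s window with both
# the sharp and the boxcar-rounded hinge basis and keeps the best fit.
breakpoint_oracle <- function(tt, y, lo, hi, h = 15) {
  sse_of <- function(x3) sum(stats::lm(y ~ tt + x3)$residuals^2)
  cand <- tt[tt >= lo & tt <= hi]
  s1 <- vapply(cand, function(cc) sse_of(pmax(tt - cc, 0)), numeric(1))
  c1 <- cand[which.min(s1)]

  keep <- tt >= c1 - 60 & tt <= c1 + 60
  t2 <- tt[keep]; y2 <- y[keep]
  cand2 <- t2[t2 > t2[1] + 5 & t2 < t2[length(t2)] - 5]
  best <- c(Inf, NA)
  for (cc in cand2) {
    u <- t2 - cc
    for (x3 in list(pmax(u, 0),
                    ifelse(u <= -h, 0, ifelse(u >= h, u, (u + h)^2 / (4 * h))))) {
      s <- sum(stats::lm(y2 ~ t2 + x3)$residuals^2)
      if (s < best[1]) best <- c(s, cc)
    }
  }
  best[2]
}
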