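#' Planted physiological profile for one simulated ramp test
#'
#' Holds the ground-truth parameters the simulator plants into a
#' breath-by-breath record: resting oxygen uptake and the 10 mL/min/W
#' work-rate gain, the oxygen uptake efficiency slope (OUES) and plateau
#' (OUEP), both ventilatory thresholds as fractions of peak VO2, peak
#' values, the VO2-plateau state, and the noise model.
#'
#' `oues_b` (the OUES intercept) is a derived quantity: the generator plants
#' the slope and the efficiency plateau, which together with the VO2
#' trajectory pin the intercept down; its realised value is reported in the
#' ground-truth record attached to each simulated series.
#'
#' @param vo2_rest Resting VO2, mL/min.
#' @param vo2_gain VO2 cost of work, mL/min per W. Default 10, the
#'   conventional ramp-cycling value.
#' @param oues_a Planted OUES slope, mL/min per log10(L/min). Must be > 0.
#' @param vt1_frac,vt2_frac Planted VT1/VT2 as fractions of peak VO2, with
#'   `0 < vt1_frac < vt2_frac < 1`.
#' @param vo2peak_rel Planted peak VO2, mL/kg/min.
#' @param ouep Planted oxygen uptake efficiency plateau, mL O2 per L VE
#'   (the maximum of the noise-free VO2/VE curve, reached at VT1).
#' @param hr_max,hr_rest Peak and resting heart rate, beats/min.
#' @param rer_max Peak respiratory exchange ratio (reached at termination).
#' @param plateau Logical: should the test end in a VO2 plateau?
#' @param plateau_fraction Achieved fraction (< 0.5) of the ramp-expected
#'   last-minute VO2 rise when `plateau` is `TRUE`.
#' @param breath_rate Breaths/min at rest and at peak, length-2 vector.
#' @param jitter_sd Log-SD of multiplicative breath-interval jitter.
#' @param noise_sd Named vector of per-channel multiplicative log-normal
#'   noise SDs (`vo2`, `vco2`, `ve`, `hr`, `peto2`, `petco2`).
#' @param tau First-order VO2 lag time constant, seconds. Default 30.
#' @param oues_b Ignored on input (see above); accepted so profiles read
#'   back from a manifest round-trip.
#' @return Object of class `physio_profile`.
#' @export
physio_profile <- function(vo2_rest = 300, vo2_gain = 10,
                           oues_a = 1500, oues_b = NA_real_,
                           vt1_frac = 0.6, vt2_frac = 0.9,
                           vo2peak_rel = 45, ouep = 40,
                           hr_max = 190, hr_rest = 70, rer_max = 1.2,
                           plateau = FALSE, plateau_fraction = 0.3,
                           breath_rate = c(15, 50), jitter_sd = 0.1,
                           noise_sd = c(vo2 = 0.05, vco2 = 0.05, ve = 0.05,
                                        hr = 0.02, peto2 = 0.01, petco2 = 0.01),
                           tau = 30) {
  if (!(vt1_frac > 0 && vt1_frac < vt2_frac && vt2_frac < 1)) {
    stop("need 0 < vt1_frac < vt2_frac < 1")
  }
  if (vo2_gain <= 0) stop("vo2_gain must be positive")
  if (oues_a <= 0) stop("oues_a must be positive")
  if (ouep <= 0) stop("ouep must be positive")
  if (isTRUE(plateau) && plateau_fraction >= 0.5) {
    stop("a planted plateau requires plateau_fraction < 0.5")
  }
  nd <- c(vo2 = 0.05, vco2 = 0.05, ve = 0.05, hr = 0.02,
          peto2 = 0.01, petco2 = 0.01)
  nd[names(noise_sd)] <- noise_sd
  structure(list(vo2_rest = vo2_rest, vo2_gain = vo2_gain, oues_a = oues_a,
                 oues_b = oues_b, vt1_frac = vt1_frac, vt2_frac = vt2_frac,
                 vo2peak_rel = vo2peak_rel, ouep = ouep, hr_max = hr_max,
                 hr_rest = hr_rest, rer_max = rer_max, plateau = plateau,
                 plateau_fraction = plateau_fraction,
                 breath_rate = breath_rate, jitter_sd = jitter_sd,
                 noise_sd = nd, tau = tau),
            class = "physio_profile")
}

# First-order lag response of VO2 demand to the ramp work profile, closed
# form. Returns a vectorised function of time (s); monotone non-decreasing.
.vo2_lag_fun <- function(profile, protocol) {
  tau <- profile$tau
  tr <- protocol$warmup_duration
  D0 <- profile$vo2_rest + profile$vo2_gain * protocol$start_load
  cc <- profile$vo2_gain * protocol$ramp_rate / 60  # mL/min per s
  L0 <- D0 + (profile$vo2_rest - D0) * exp(-tr / tau)
  function(t) {
    warm <- D0 + (profile$vo2_rest - D0) * exp(-pmin(t, tr) / tau)
    s <- pmax(t - tr, 0)
    ramp <- D0 + cc * s - cc * tau * (1 - exp(-s / tau)) +
      (L0 - D0) * exp(-s / tau)
    ifelse(t <= tr, warm, ramp)
  }
}

# Mean of f over [a, b] by the trapezoid rule on a fine grid.
.mean_over <- function(f, a, b, dt = 0.25) {
  tt <- seq(a, b, by = dt)
  v <- f(tt)
  sum((v[-1] + v[-length(v)]) / 2 * diff(tt)) / (b - a)
}

# OLS slope/intercept of y on x without model frames.
.ols2 <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  b1 <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(slope = b1, intercept = yb - b1 * xb)
}

#' Simulate one breath-by-breath ramp test
#'
#' Generates a full breath record with planted ground truth. The noise-free
#' construction: work rate follows the protocol; VO2 is the first-order lag
#' (time constant `tau`) of `vo2_rest + vo2_gain * P(t)`, capped at the
#' planted peak; termination is the moment the trajectory reaches the peak,
#' or, when a plateau is planted, the later moment at which the last-minute
#' rise has decayed to `plateau_fraction` of the ramp-expected rise. The
#' ventilatory equivalent VE/VO2 is exactly piecewise linear in time with
#' its nadir (the planted OUEP, 1000/ouep) at the VT1 time; its end value is
#' solved by root-finding so that the ordinary least-squares regression of
#' VO2 on log10(VE) over all generated breaths returns exactly the planted
#' OUES slope. RER rises piecewise linearly from 0.85 to `rer_max` with a
#' slope drop at VT2, which gives VE/VCO2 a distinct upward hinge there;
#' PetO2 rises from VT1 and PetCO2 falls from VT2. Heart rate is linear in
#' the VO2 fraction up to `hr_max`. Breath timestamps follow a linear
#' rest-to-peak breath-rate model with multiplicative jitter; measurement
#' noise is per-channel multiplicative log-normal.
#'
#' The same `(profile, participant, protocol, seed)` always yields an
#' identical series. The planted/realised truth is attached as attribute
#' `"ground_truth"` (see [ground_truth()]).
#'
#' @param profile A [physio_profile()].
#' @param participant A [participant()] (body mass scales the peak).
#' @param protocol A [ramp_protocol()].
#' @param seed Integer seed.
#' @return A [breath_series()] with a `ground_truth` attribute.
#' @export
simulate_test <- function(profile, participant, protocol, seed) {
  stopifnot(inherits(profile, "physio_profile"),
            inherits(participant, "cpet_participant"),
            inherits(protocol, "ramp_protocol"))
  set.seed(as.integer(seed %% 2147483647L))
  mass <- participant$body_mass
  vo2cap <- profile$vo2peak_rel * mass
  tr <- protocol$warmup_duration
  D0 <- profile$vo2_rest + profile$vo2_gain * protocol$start_load
  if (vo2cap <= 1.02 * D0) {
    stop("impossible profile: planted VO2peak (", round(vo2cap),
         " mL/min) does not exceed the warm-up demand (", round(D0), " mL/min)")
  }
  lag <- .vo2_lag_fun(profile, protocol)

  t_cap <- stats::uniroot(function(t) lag(t) - vo2cap,
                          interval = c(tr, tr + 7200),
                          tol = 1e-8, extendInt = "upX")$root
  vo2_free <- function(t) pmin(lag(t), vo2cap)
  expected_rise <- profile$vo2_gain * protocol$ramp_rate  # mL/min over 1 min

  te <- t_cap
  if (isTRUE(profile$plateau)) {
    rise <- function(tend) {
      .mean_over(vo2_free, tend - 60, tend) -
        .mean_over(vo2_free, tend - 120, tend - 60)
    }
    target <- profile$plateau_fraction * expected_rise
    if (t_cap - tr >= 150 && rise(t_cap) > target) {
      te <- stats::uniroot(function(tt) rise(tt) - target,
                           interval = c(t_cap, t_cap + 119.5), tol = 1e-6)$root
    }  # else: ramp too short to shape a plateau; test ends at the cap
  }

  vt_time <- function(frac) {
    stats::uniroot(function(t) vo2_free(t) - frac * vo2cap,
                   interval = c(0, t_cap), tol = 1e-9)$root
  }
  if (profile$vt1_frac * vo2cap <= profile$vo2_rest * 1.001) {
    stop("impossible profile: VT1 below resting VO2")
  }
  t1 <- vt_time(profile$vt1_frac)
  t2 <- vt_time(profile$vt2_frac)

  # breath timestamps: rate linear in VO2 fraction, log-normal jitter
  frac_of <- function(v) pmin(pmax((v - profile$vo2_rest) /
                                     (vo2cap - profile$vo2_rest), 0), 1)
  br <- profile$breath_rate
  tb <- numeric(ceiling(te / (60 / max(br))) + 50L)
  tb[1] <- 0
  i <- 1L
  while (tb[i] < te) {
    rate <- br[1] + (br[2] - br[1]) * frac_of(vo2_free(tb[i]))
    step <- 60 / rate * exp(stats::rnorm(1, 0, profile$jitter_sd))
    i <- i + 1L
    tb[i] <- tb[i - 1L] + step
  }
  tb <- tb[seq_len(i)]
  tb <- tb[tb <= te]

  y <- vo2_free(tb)

  # ventilatory equivalent: piecewise linear with its nadir (the planted
  # OUEP) at t1 and a doubling of slope at t2 (respiratory-compensation
  # acceleration); the end value is solved so the whole-test OLS of VO2 on
  # log10(VE) has slope exactly oues_a
  E1 <- 1000 / profile$ouep
  eq_drop <- 1.5
  rho <- 2  # terminal-over-isocapnic slope ratio
  eq_fun <- function(t, eq_end) {
    s1 <- (eq_end - E1) / ((t2 - t1) + rho * (te - t2))
    ifelse(t <= t1,
           E1 + eq_drop * (t1 - t) / t1,
           ifelse(t <= t2,
                  E1 + s1 * (t - t1),
                  E1 + s1 * (t2 - t1) + rho * s1 * (t - t2)))
  }
  slope_of <- function(eq_end) {
    .ols2(log10(y * eq_fun(tb, eq_end) / 1000), y)[["slope"]]
  }
  f <- function(u) slope_of(E1 + exp(u)) - profile$oues_a
  lo <- log(0.05); hi <- log(1e6)
  if (f(lo) < 0) {
    stop("impossible profile: planted OUES slope ", profile$oues_a,
         " exceeds what the test's VO2 span supports")
  }
  u <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  eq_end <- E1 + exp(u)
  eq_b <- eq_fun(tb, eq_end)
  ve <- y * eq_b / 1000
  fit <- .ols2(log10(ve), y)

  # RER: piecewise linear 0.85 -> rer_max with knots at t1 and t2; the slope
  # drop at t2 puts the upward VE/VCO2 hinge there
  rer_knots_t <- c(0, t1, t2, te)
  rer_knots_v <- c(0.85, 0.88, 0.97 * profile$rer_max, profile$rer_max)
  if (any(diff(rer_knots_v) <= 0)) {
    stop("impossible profile: rer_max ", profile$rer_max,
         " too low for a monotone RER trajectory")
  }
  rer_fun <- function(t) stats::approx(rer_knots_t, rer_knots_v, xout = t,
                                       rule = 2)$y
  vco2 <- rer_fun(tb) * y

  hr <- profile$hr_rest + (profile$hr_max - profile$hr_rest) * frac_of(y)
  peto2 <- ifelse(tb <= t1, 90, 90 + 18 * (tb - t1) / (te - t1))
  petco2 <- ifelse(tb <= t2, 40, 40 - 7 * (tb - t2) / (te - t2))
  power <- protocol_power(protocol, tb)

  # realised noise-free truth, before noise is applied
  grid <- seq(0, te, by = 1)
  oue_grid <- 1000 / eq_fun(grid, eq_end)
  truth_ouep <- max(.roll_mean(oue_grid, 91L))
  ramp_b <- tb >= tr + 15 & tb <= te - 15  # matches the O2/W estimator trim
  truth <- list(
    vo2peak_abs = vo2cap, vo2peak_rel = profile$vo2peak_rel,
    p_peak = protocol_power(protocol, te),
    hr_max = profile$hr_max, rer_max = profile$rer_max,
    plateau = isTRUE(profile$plateau) && te > t_cap,
    oues_a = profile$oues_a, oues_b = unname(fit["intercept"]),
    oues_rel = profile$oues_a / mass,
    ouep = truth_ouep, ouep_pointwise_max = 1000 / min(eq_fun(grid, eq_end)),
    t_vt1 = t1, t_vt2 = t2,
    vo2_vt1_abs = profile$vt1_frac * vo2cap,
    vo2_vt2_abs = profile$vt2_frac * vo2cap,
    vo2_vt1_rel = profile$vt1_frac * profile$vo2peak_rel,
    vo2_vt2_rel = profile$vt2_frac * profile$vo2peak_rel,
    oue_vt1 = 1000 / eq_fun(t1, eq_end), oue_vt2 = 1000 / eq_fun(t2, eq_end),
    p_vt1 = protocol_power(protocol, t1), p_vt2 = protocol_power(protocol, t2),
    o2_per_watt = unname(.ols2(power[ramp_b], y[ramp_b])["slope"]),
    t_cap = t_cap, termination = te)

  ns <- profile$noise_sd
  noisy <- function(x, ch) x * exp(stats::rnorm(length(x), 0, ns[[ch]]))
  rec <- data.frame(
    t = tb,
    vo2 = noisy(y, "vo2"), vco2 = noisy(vco2, "vco2"), ve = noisy(ve, "ve"),
    hr = pmin(pmax(noisy(hr, "hr"), 40), 250),
    peto2 = noisy(peto2, "peto2"), petco2 = noisy(petco2, "petco2"),
    power = power)
  out <- breath_series(rec, list(warmup_start = 0, ramp_start = tr,
                                 termination = te))
  attr(out, "ground_truth") <- truth
  out
}

#' Planted ground truth of a simulated series
#'
#' @param series A series produced by [simulate_test()].
#' @return Named list of the planted / realised noise-free quantities
#'   (peaks, OUES slope and implied intercept, OUEP, threshold times and
#'   values, O2-per-watt slope, plateau state).
#' @export
ground_truth <- function(series) attr(series, "ground_truth")

# rolling mean of x over windows of `width` consecutive samples
.roll_mean <- function(x, width) {
  n <- length(x)
  if (n < width) return(mean(x))
  cs <- cumsum(c(0, x))
  (cs[(width + 1):(n + 1)] - cs[1:(n - width + 1)]) / width
}
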