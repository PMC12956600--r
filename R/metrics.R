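#' Peak values of a smoothed breath series
#'
#' Peak VO2 is defined as the maximum of the (30-s moving-average) smoothed
#' VO2 channel over the whole test; peak power is the work rate at
#' termination, and HRmax / RERmax are the channel maxima of the smoothed
#' series. Pass a series already smoothed with [moving_average()].
#'
#' @param series A smoothed [breath_series()].
#' @param body_mass Body mass in kg, for the per-kilogram peak.
#' @return List of class `peak_result`: `vo2peak_abs` (L/min),
#'   `vo2peak_rel` (mL/kg/min), `p_peak` (W), `hr_max`, `rer_max`, and the
#'   time of the VO2 peak (`t_peak`, earliest maximum).
#' @export
compute_vo2peak <- function(series, body_mass) {
  stopifnot(inherits(series, "breath_series"))
  if (series$t[nrow(series)] - series$t[1] < 30) {
    stop("series shorter than the smoothing window (30 s)")
  }
  i <- which.max(series$vo2)  # earliest maximum on ties
  hr <- series$hr[!is.na(series$hr)]
  structure(list(
    vo2peak_abs = series$vo2[i] / 1000,
    vo2peak_rel = series$vo2[i] / body_mass,
    t_peak = series$t[i],
    p_peak = series$power[nrow(series)],
    hr_max = if (length(hr)) max(hr) else NA_real_,
    rer_max = max(series$vco2 / series$vo2)),
    class = "peak_result")
}

#' Ramp-aware VO2 plateau detection
#'
#' The observed rise is the mean VO2 over the final 60 s minus the mean over
#' the preceding 60 s (computed on a 1-s interpolation grid); the expected
#' rise is `gain * ramp_rate` mL/min (one minute of ramp at the conventional
#' 10 mL/min/W cost). A plateau is called when the observed rise is strictly
#' below `frac` (default 0.5) of the expected rise.
#'
#' @param series A smoothed [breath_series()].
#' @param protocol The [ramp_protocol()] of the test (supplies the ramp
#'   rate).
#' @param gain Assumed VO2 cost of work, mL/min/W. Default 10.
#' @param frac Plateau fraction threshold. Default 0.5, strict `<`.
#' @return List of class `plateau_result`: `evaluable`, `plateau`,
#'   `observed_rise`, `expected_rise` (mL/min).
#' @export
detect_plateau <- function(series, protocol, gain = 10, frac = 0.5) {
  stopifnot(inherits(series, "breath_series"))
  ph <- phases(series)
  ramp_len <- min(ph$termination, series$t[nrow(series)]) - ph$ramp_start
  expected <- gain * protocol$ramp_rate
  if (ramp_len < 120) {
    return(structure(list(evaluable = FALSE, plateau = NA,
                          observed_rise = NA_real_, expected_rise = expected),
                     class = "plateau_result"))
  }
  g <- resample_to_grid(series, dt = 1)
  te <- g$t[nrow(g)]
  last <- mean(g$vo2[g$t > te - 60 & g$t <= te])
  prev <- mean(g$vo2[g$t > te - 120 & g$t <= te - 60])
  observed <- last - prev
  structure(list(evaluable = TRUE, plateau = observed < frac * expected,
                 observed_rise = observed, expected_rise = expected),
            class = "plateau_result")
}

#' Secondary exhaustion criteria
#'
#' Adults (MTA/WTA) are classified as exhausted when RERmax >= 1.13; for
#' children, where no validated RER criterion exists, the conventional
#' HRmax >= 95% of 195 beats/min (185.25) is applied. Both thresholds are
#' inclusive and configurable.
#'
#' @param peak A [compute_vo2peak()] result (or any list with `rer_max` /
#'   `hr_max`).
#' @param group Cohort label (`"children"` uses the HR criterion; `"MTA"`
#'   and `"WTA"` the RER criterion).
#' @param rer_crit Adult RERmax criterion. Default 1.13.
#' @param hr_frac,hr_ref Children's criterion: `hr_frac * hr_ref`.
#'   Defaults 0.95 and 195.
#' @return Logical scalar with attribute `criterion` describing the rule
#'   applied.
#' @export
check_exhaustion <- function(peak, group, rer_crit = 1.13, hr_frac = 0.95,
                             hr_ref = 195) {
  group <- match.arg(group, c("children", "MTA", "WTA"))
  if (group == "children") {
    if (is.null(peak$hr_max) || is.na(peak$hr_max)) {
      stop("exhaustion check for children needs the hr channel (hr_max missing)")
    }
    out <- peak$hr_max >= hr_frac * hr_ref
    attr(out, "criterion") <- sprintf("HRmax >= %.2f (%.0f%% of %g bpm)",
                                      hr_frac * hr_ref, 100 * hr_frac, hr_ref)
  } else {
    if (is.null(peak$rer_max) || is.na(peak$rer_max)) {
      stop("exhaustion check for adults needs the rer_max value (vco2/vo2 missing)")
    }
    out <- peak$rer_max >= rer_crit
    attr(out, "criterion") <- sprintf("RERmax >= %g", rer_crit)
  }
  out
}

#' Per-breath oxygen uptake efficiency
#'
#' OUE = VO2 / VE, in mL O2 per litre of ventilation, aligned to the breath
#' timestamps.
#'
#' @param series A [breath_series()].
#' @return Numeric vector of OUE values.
#' @export
compute_oue <- function(series) {
  stopifnot(inherits(series, "breath_series"))
  if (any(series$ve <= 0)) stop("ve must be positive for OUE")
  series$vo2 / series$ve
}

#' Oxygen uptake efficiency plateau (OUEP)
#'
#' The highest 90-s average of consecutive OUE values. Because breath
#' timestamps are irregular, the OUE series is first interpolated onto a 1-s
#' grid; windows `[s, s + 90]` are evaluated at every 1-s offset over the
#' whole test (warm-up through termination) and ties go to the earliest
#' window.
#'
#' @param series A smoothed [breath_series()].
#' @param window Window length in seconds. Default 90.
#' @return The OUEP (mL O2 / L), with attribute `t_start`, the start of the
#'   best window; `NA` with attribute `evaluable = FALSE` if the test is
#'   shorter than the window.
#' @export
compute_ouep <- function(series, window = 90) {
  stopifnot(inherits(series, "breath_series"))
  if (series$t[nrow(series)] - series$t[1] < window) {
    return(structure(NA_real_, evaluable = FALSE))
  }
  g <- resample_to_grid(series, dt = 1)
  oue <- g$vo2 / g$ve
  rm90 <- .roll_mean(oue, as.integer(window) + 1L)
  i <- which.max(rm90)  # earliest on ties
  structure(rm90[i], t_start = g$t[i], evaluable = TRUE)
}

#' Oxygen uptake efficiency slope (OUES)
#'
#' Ordinary least-squares regression of VO2 (mL/min) on the common logarithm
#' of VE (L/min). The default scope is the whole test (all exercise data,
#' warm-up included); `scope = "ramp"` restricts the fit to the ramp phase.
#'
#' @param series A smoothed [breath_series()].
#' @param scope `"whole"` (default) or `"ramp"`.
#' @param body_mass Optional body mass (kg) for the per-kilogram slope.
#' @return List of class `oues_result`: `oues_a` (slope, mL/min per
#'   log10(L/min)), `oues_b` (intercept, mL/min), `oues_rel` (slope /
#'   body mass), `n` breaths used.
#' @export
compute_oues <- function(series, scope = c("whole", "ramp"),
                         body_mass = NA_real_) {
  stopifnot(inherits(series, "breath_series"))
  scope <- match.arg(scope)
  s <- if (scope == "ramp") .clip_series(series, from = phases(series)$ramp_start)
       else series
  if (nrow(s) < 10L) stop("need at least 10 breaths in scope for the OUES fit")
  if (any(s$ve <= 0)) stop("ve must be positive for the OUES fit")
  x <- log10(s$ve)
  if (stats::sd(x) < 1e-12) stop("degenerate VE (all equal): singular OUES fit")
  fit <- .ols2(x, s$vo2)
  structure(list(oues_a = unname(fit["slope"]), oues_b = unname(fit["intercept"]),
                 oues_rel = unname(fit["slope"]) / body_mass, n = nrow(s)),
            class = "oues_result")
}

#' Exercise efficiency: VO2 per watt
#'
#' OLS slope of smoothed VO2 (mL/min) on work rate (W) over the ramp phase
#' (the table-convention reading of O2/P in mL/min/W). The first and last
#' `trim` seconds of the ramp are excluded so that smoothing-window
#' boundary effects do not contaminate the fit. A peak-ratio alternative,
#' `max VO2 / peak power`, is available via `method`.
#'
#' @param series A smoothed [breath_series()].
#' @param method `"slope"` (default) or `"peak_ratio"`.
#' @param trim Seconds trimmed from each end of the ramp for the slope fit.
#'   Default 15 (half the standard smoothing window).
#' @return O2 per watt, mL/min/W.
#' @export
compute_o2_per_watt <- function(series, method = c("slope", "peak_ratio"),
                                trim = 15) {
  stopifnot(inherits(series, "breath_series"))
  method <- match.arg(method)
  ramp <- .clip_series(series, from = phases(series)$ramp_start + trim,
                       to = series$t[nrow(series)] - trim)
  if (nrow(ramp) < 3L || stats::sd(ramp$power) < 1e-12) {
    stop("no ramp (constant power): O2/W slope undefined")
  }
  if (method == "peak_ratio") {
    return(max(series$vo2) / series$power[nrow(series)])
  }
  unname(.ols2(ramp$power, ramp$vo2)["slope"])
}
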