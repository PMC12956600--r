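# Continuous two-segment (hinge) least squares: for a candidate breakpoint c
# the model is y ~ 1 + t + max(t - c, 0). Candidates are scanned on a grid
# and the SSE-minimising breakpoint returned, together with the F-ratio of
# the hinge model against a single line.
.hinge_scan <- function(t, y, candidates) {
  n <- length(t)
  sse1 <- sum(stats::lm.fit(cbind(1, t), y)$residuals^2)
  best <- list(sse = Inf, c = NA_real_, coef = NULL)
  for (cc in candidates) {
    X <- cbind(1, t, pmax(t - cc, 0))
    f <- stats::.lm.fit(X, y)
    sse <- sum(f$residuals^2)
    if (sse < best$sse) best <- list(sse = sse, c = cc, coef = f$coefficients)
  }
  f_ratio <- if (best$sse <= 0) Inf else
    ((sse1 - best$sse) / 2) / (best$sse / max(n - 4L, 1L))
  list(breakpoint = best$c, coef = best$coef, sse = best$sse,
       sse_line = sse1, f_ratio = f_ratio)
}

.interp_at <- function(t, x, t0) {
  stats::approx(t, x, xout = t0, rule = 2, ties = mean)$y
}

.accepted <- function(fit, f_gate, rising = TRUE) {
  !is.null(fit) && is.finite(fit$f_ratio) && fit$f_ratio >= f_gate &&
    ((rising && fit$coef[3] > 0) || (!rising && fit$coef[3] < 0))
}

# Joint threshold estimation on the gridded ramp data. The equivalents
# carry both transitions (VE/VO2: nadir at VT1; VE/VCO2: slope-up at VT2),
# and a single two-segment model cannot represent a three-segment channel,
# so the VT2 fit is anchored past the VE/VO2 nadir and the two fits
# condition on each other:
#   1. provisional VT2 on VE/VCO2 over data from the right edge of the
#      VE/VO2 nadir basin onward (the last time the equivalent sits within
#      5% of its range above the minimum - robust to noise in the flat
#      pre-VT1 stretch, and just past the smoothing-rounded corner);
#   2. VT1 on VE/VO2 over data before the provisional VT2 (full ramp if
#      not found);
#   3. VT2 refitted from max(nadir edge, VT1 + 30 s) onward.
.vt_pipeline <- function(g, lo, hi, f_gate) {
  eqo2 <- g$ve * 1000 / g$vo2
  eqco2 <- g$ve * 1000 / g$vco2

  band <- min(eqo2) + 0.05 * (max(eqo2) - min(eqo2))
  anchor <- g$t[max(which(eqo2 <= band))]

  scan_from <- function(t_from, y) {
    keep <- g$t >= t_from
    if (sum(keep) < 30L) return(NULL)
    tt <- g$t[keep]
    cand <- tt[tt >= max(lo, tt[1] + 10) & tt <= hi]
    if (length(cand) < 3L) return(NULL)
    .hinge_scan(tt, y[keep], cand)
  }

  vt2 <- scan_from(anchor, eqco2)
  if (!.accepted(vt2, f_gate)) vt2 <- NULL

  gl_max <- if (!is.null(vt2)) vt2$breakpoint else g$t[nrow(g)]
  keep1 <- g$t <= gl_max
  vt1 <- NULL
  if (sum(keep1) >= 30L) {
    tt <- g$t[keep1]
    cand <- tt[tt >= lo & tt <= hi]
    if (length(cand) >= 3L) vt1 <- .hinge_scan(tt, eqo2[keep1], cand)
  }
  if (!.accepted(vt1, f_gate)) vt1 <- NULL

  anchor2 <- anchor
  if (!is.null(vt1)) {
    anchor2 <- max(anchor, vt1$breakpoint + 30)
    vt2b <- scan_from(anchor2, eqco2)
    if (.accepted(vt2b, f_gate)) vt2 <- vt2b
  }

  # second stage: re-localise each accepted breakpoint inside a local
  # window with a smoothing-aware hinge basis. A centred boxcar of width 2h
  # turns the hinge max(t - c, 0) into the quadratic rounding q(t - c), so
  # scanning c with the basis [1, t, q(t - c)] represents the smoothed
  # corner exactly and stays unbiased even when one arm of the corner is
  # short (a transition close to termination), where the sharp-hinge scan
  # drifts by up to half the smoothing window.
  refine <- function(fit, y, from, to, h = 15) {
    if (is.null(fit)) return(NULL)
    keep <- g$t >= max(from, fit$breakpoint - 60) &
      g$t <= min(to, fit$breakpoint + 60)
    if (sum(keep) < 30L) return(fit)
    tt <- g$t[keep]
    yk <- y[keep]
    cand <- tt[tt > tt[1] + 5 & tt < tt[length(tt)] - 5]
    if (length(cand) < 3L) return(fit)
    best <- list(sse = Inf, c = NA_real_, slope = NA_real_)
    for (cc in cand) {
      u <- tt - cc
      sharp <- pmax(u, 0)
      round_ <- ifelse(u <= -h, 0, ifelse(u >= h, u, (u + h)^2 / (4 * h)))
      for (x3 in list(sharp, round_)) {
        f <- stats::.lm.fit(cbind(1, tt, x3), yk)
        sse <- sum(f$residuals^2)
        if (sse < best$sse) {
          best <- list(sse = sse, c = cc, slope = f$coefficients[3])
        }
      }
    }
    if (is.finite(best$sse) && !is.na(best$slope) && best$slope > 0) {
      fit$breakpoint <- best$c
    }
    fit
  }
  t_end <- g$t[nrow(g)]
  list(vt1 = refine(vt1, eqo2, g$t[1], gl_max),
       vt2 = refine(vt2, eqco2, anchor2, t_end),
       keep1 = keep1)
}

#' Automated ventilatory threshold detection
#'
#' Locates VT1 and VT2 on the standard ventilatory-equivalent panel by
#' two-segment piecewise-linear least squares on a 1-s interpolation grid
#' of the ramp phase:
#'
#' * **VT1** - breakpoint where VE/VO2 leaves its nadir and rises, fitted
#'   over the ramp data before the detected VT2; cross-checked (advisory)
#'   against the V-slope breakpoint of VCO2 versus VO2.
#' * **VT2** - breakpoint where VE/VCO2 begins its steeper sustained rise,
#'   fitted over the data from the detected VT1 onward; cross-checked
#'   (advisory) against the onset of PetCO2 decline when that channel is
#'   present.
#'
#' Because each equivalent also carries the other transition, the two fits
#' condition on each other and are iterated once (provisional VT2 from the
#' VE/VO2 nadir, VT1 below it, VT2 refitted above the detected VT1). Each
#' accepted breakpoint is then re-localised inside a +/-60 s window by a
#' second scan that fits both a sharp hinge and a smoothing-rounded hinge
#' (the exact shape a centred 30-s window gives a piecewise-linear signal)
#' and keeps whichever basis fits better; the local window removes the
#' leverage of far-field curvature, and the rounded basis keeps the
#' estimate unbiased when one arm of the corner is short (a transition
#' close to termination). The final half smoothing window of the record is
#' excluded throughout, because truncated windows bend the smoothed
#' equivalents there. A breakpoint is accepted only when the global hinge
#' model beats a single line by the F-ratio `f_gate` and the slope change
#' has the expected sign; otherwise a threshold-not-found result is
#' returned (`found = FALSE`), not an error.
#'
#' @param series A smoothed [breath_series()].
#' @param kind `"VT1"` or `"VT2"`.
#' @param body_mass Body mass (kg) for per-kilogram VO2 at the threshold.
#' @param f_gate Minimum F-ratio for accepting a breakpoint. Default 4.
#' @param window Fractions of the ramp within which a breakpoint may lie.
#'   Default `c(0.05, 0.95)`.
#' @return Object of class `threshold_point`: `kind`, `found`, `t`,
#'   `vo2_abs` (mL/min), `vo2_rel` (mL/kg/min), `oue`, `power`, `f_ratio`,
#'   `detection` (`"auto"`), plus the advisory cross-check time (`cross_t`,
#'   `NA` when unavailable).
#' @export
detect_vt <- function(series, kind = c("VT1", "VT2"), body_mass = NA_real_,
                      f_gate = 4, window = c(0.05, 0.95)) {
  stopifnot(inherits(series, "breath_series"))
  kind <- match.arg(kind)
  ph <- phases(series)
  g <- resample_to_grid(series, dt = 1)
  # drop the final half smoothing window: centred windows are truncated
  # there, which bends the smoothed equivalents down and drags breakpoints
  g <- g[g$t >= ph$ramp_start & g$t <= max(g$t) - 15, , drop = FALSE]
  if (nrow(g) < 60L) stop("ramp phase too short for threshold detection")
  ramp_span <- g$t[nrow(g)] - g$t[1]
  lo <- g$t[1] + window[1] * ramp_span
  hi <- g$t[1] + window[2] * ramp_span

  est <- .vt_pipeline(g, lo, hi, f_gate)
  fit <- if (kind == "VT1") est$vt1 else est$vt2

  cross_t <- if (kind == "VT1") {
    # advisory V-slope: VCO2 vs VO2 breakpoint, mapped back to time
    gl <- g[est$keep1, , drop = FALSE]
    vs <- .hinge_scan(gl$vo2, gl$vco2,
                      stats::quantile(gl$vo2, seq(0.05, 0.95, length.out = 80)))
    if (.accepted(vs, f_gate)) .interp_at(gl$vo2, gl$t, vs$breakpoint)
    else NA_real_
  } else {
    # advisory onset of end-tidal CO2 decline
    if (all(is.na(g$petco2))) NA_real_ else {
      ps <- .hinge_scan(g$t, g$petco2, g$t[g$t >= lo & g$t <= hi])
      if (.accepted(ps, f_gate, rising = FALSE)) ps$breakpoint else NA_real_
    }
  }

  if (is.null(fit)) {
    return(structure(list(kind = kind, found = FALSE, t = NA_real_,
                          vo2_abs = NA_real_, vo2_rel = NA_real_,
                          oue = NA_real_, power = NA_real_,
                          f_ratio = NA_real_, cross_t = cross_t,
                          detection = "auto"),
                     class = "threshold_point"))
  }
  t0 <- fit$breakpoint
  vo2_at <- .interp_at(g$t, g$vo2, t0)
  structure(list(kind = kind, found = TRUE, t = t0,
                 vo2_abs = vo2_at, vo2_rel = vo2_at / body_mass,
                 oue = vo2_at / .interp_at(g$t, g$ve, t0),
                 power = .interp_at(g$t, g$power, t0),
                 f_ratio = fit$f_ratio, cross_t = cross_t,
                 detection = "auto"),
            class = "threshold_point")
}

#' @export
print.threshold_point <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("<threshold_point> %s: not found (F=%s)\n", x$kind,
                format(x$f_ratio)))
  } else {
    cat(sprintf(
      "<threshold_point> %s at %.1f s: VO2 %.0f mL/min (%.1f mL/kg/min), OUE %.1f, P %.0f W\n",
      x$kind, x$t, x$vo2_abs, x$vo2_rel, x$oue, x$power))
  }
  invisible(x)
}
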