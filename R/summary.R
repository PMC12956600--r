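#' Summarise one CPET: every per-participant derived metric
#'
#' Runs the full per-test pipeline: 30-s moving-average smoothing, peak
#' values, ramp-aware plateau detection, exhaustion classification, OUES,
#' OUEP, O2-per-watt, and automated (or manually imported) ventilatory
#' thresholds, then assembles the derived ratios. A participant who fails
#' the exhaustion criterion keeps all submaximal fields but is marked
#' `include_maximal = FALSE`, so downstream analyses can exclude them from
#' peak-dependent outcomes only. Thresholds that are not found leave the
#' threshold-dependent fields `NA`; the summary is still returned.
#'
#' @param participant A [participant()].
#' @param series A raw [breath_series()] (smoothing is applied here).
#' @param protocol The test's [ramp_protocol()].
#' @param smooth_window Moving-average window, seconds. Default 30.
#' @param oues_scope `"whole"` (default) or `"ramp"`, see [compute_oues()].
#' @param vt_manual Optional numeric vector `c(t1, t2)` of rater-set
#'   threshold times (s); when supplied the detector is bypassed and the
#'   threshold points are interpolated at these times with detection tag
#'   `"manual-import"` (`NA` entries fall back to auto detection).
#' @param ... Passed on to [detect_vt()] (e.g. `f_gate`).
#' @return Object of class `cpet_summary` (a named list); see
#'   [as.data.frame.cpet_summary()] for the flat row form.
#' @export
summarize_test <- function(participant, series, protocol,
                           smooth_window = 30, oues_scope = "whole",
                           vt_manual = NULL, ...) {
  stopifnot(inherits(participant, "cpet_participant"))
  sm <- moving_average(series, smooth_window)
  mass <- participant$body_mass

  peak <- compute_vo2peak(sm, mass)
  plateau <- detect_plateau(sm, protocol)
  exhausted <- check_exhaustion(peak, participant$group)
  oues <- compute_oues(sm, scope = oues_scope, body_mass = mass)
  ouep <- compute_ouep(sm)
  o2w <- compute_o2_per_watt(sm)

  manual_point <- function(kind, t0) {
    g <- resample_to_grid(sm, dt = 1)
    vo2_at <- .interp_at(g$t, g$vo2, t0)
    structure(list(kind = kind, found = TRUE, t = t0, vo2_abs = vo2_at,
                   vo2_rel = vo2_at / mass,
                   oue = vo2_at / .interp_at(g$t, g$ve, t0),
                   power = .interp_at(g$t, g$power, t0),
                   f_ratio = NA_real_, cross_t = NA_real_,
                   detection = "manual-import"),
              class = "threshold_point")
  }
  vt1 <- if (!is.null(vt_manual) && is.finite(vt_manual[1])) {
    manual_point("VT1", vt_manual[1])
  } else detect_vt(sm, "VT1", body_mass = mass, ...)
  vt2 <- if (!is.null(vt_manual) && length(vt_manual) > 1 &&
             is.finite(vt_manual[2])) {
    manual_point("VT2", vt_manual[2])
  } else detect_vt(sm, "VT2", body_mass = mass, ...)

  pct <- function(a, b) if (is.na(a) || is.na(b)) NA_real_ else 100 * a / b
  structure(list(
    participant = participant,
    peak = peak, plateau = plateau, exhausted = as.logical(exhausted),
    include_maximal = as.logical(exhausted),
    oues = oues, ouep = as.numeric(ouep), o2_per_watt = o2w,
    vt1 = vt1, vt2 = vt2,
    vt1_over_vo2peak = pct(vt1$vo2_rel, peak$vo2peak_rel),
    vt2_over_vo2peak = pct(vt2$vo2_rel, peak$vo2peak_rel),
    p_vt1_over_ppeak = pct(vt1$power, peak$p_peak),
    p_vt2_over_ppeak = pct(vt2$power, peak$p_peak),
    ouep_over_vo2peak = as.numeric(ouep) / peak$vo2peak_abs),
    class = "cpet_summary")
}

#' Flatten a CPET summary into a one-row data frame
#'
#' Column names carry explicit unit suffixes; this is the row format used by
#' [outcome_matrix()] and the written reports.
#'
#' @param x A `cpet_summary`.
#' @param ... Unused.
#' @return A one-row data frame.
#' @export
as.data.frame.cpet_summary <- function(x, ...) {
  p <- x$participant
  data.frame(
    id = p$id, group = p$group, sex = p$sex, age_y = p$age,
    body_mass_kg = p$body_mass,
    vo2peak_abs_l_min = x$peak$vo2peak_abs,
    vo2peak_rel_ml_kg_min = x$peak$vo2peak_rel,
    p_peak_w = x$peak$p_peak, hr_max_bpm = x$peak$hr_max,
    rer_max = x$peak$rer_max,
    plateau = isTRUE(x$plateau$plateau),
    exhausted = x$exhausted, include_maximal = x$include_maximal,
    vo2_vt1_rel_ml_kg_min = x$vt1$vo2_rel,
    vo2_vt2_rel_ml_kg_min = x$vt2$vo2_rel,
    vt1_over_vo2peak_pct = x$vt1_over_vo2peak,
    vt2_over_vo2peak_pct = x$vt2_over_vo2peak,
    oues_l_min = x$oues$oues_a / 1000,
    oues_rel_ml_min_kg = x$oues$oues_rel,
    ouep_ml_l = x$ouep,
    ouep_over_vo2peak_pct = x$ouep_over_vo2peak,
    oue_vt1_ml_l = x$vt1$oue, oue_vt2_ml_l = x$vt2$oue,
    o2_per_watt_ml_min_w = x$o2_per_watt,
    p_vt1_over_ppeak_pct = x$p_vt1_over_ppeak,
    p_vt2_over_ppeak_pct = x$p_vt2_over_ppeak,
    stringsAsFactors = FALSE)
}

#' @export
print.cpet_summary <- function(x, ...) {
  p <- x$participant
  cat(sprintf("<cpet_summary> %s (%s, %s)\n", p$id, p$group, p$sex))
  cat(sprintf("  VO2peak %.2f L/min (%.1f mL/kg/min), Ppeak %.0f W, RERmax %.2f, HRmax %.0f\n",
              x$peak$vo2peak_abs, x$peak$vo2peak_rel, x$peak$p_peak,
              x$peak$rer_max, x$peak$hr_max))
  cat(sprintf("  plateau: %s; exhausted: %s\n",
              ifelse(isTRUE(x$plateau$evaluable),
                     as.character(x$plateau$plateau), "not evaluable"),
              x$exhausted))
  cat(sprintf("  OUES %.0f mL/min/log10(L/min) (rel %.1f), OUEP %.1f mL/L, O2/W %.2f\n",
              x$oues$oues_a, x$oues$oues_rel, x$ouep, x$o2_per_watt))
  for (vt in list(x$vt1, x$vt2)) print(vt)
  invisible(x)
}
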