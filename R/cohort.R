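#' Cohort sampling specification
#'
#' Distributions (mean, SD, and truncation bounds) from which
#' [generate_cohort()] draws planted per-participant parameters. The three
#' built-in groups are calibrated to the study cohorts they emulate:
#' children 7-11 y, moderately trained adults (MTA) and well-trained adults
#' (WTA), with group-level anthropometrics, relative peak VO2, OUES, OUEP
#' and threshold fractions anchored at the respective descriptive means and
#' SDs. Quantities the descriptive tables do not report (resting VO2, peak
#' heart rate, peak RER, plateau prevalence) use field-typical values.
#'
#' Children's OUES is sampled on the per-kilogram scale (`oues_mode =
#' "rel"`, mean 29.5 mL/min/kg) which reproduces both the relative and the
#' absolute group means; the adult groups sample the absolute slope.
#'
#' @param group `"children"`, `"MTA"` or `"WTA"`.
#' @param n Default cohort size override (the built-in sizes are 18/18/19).
#' @param ... Named overrides of any spec entry, e.g.
#'   `oues = c(mean = 1140, sd = 0)` to plant a fixed OUES, or
#'   `noise_sd = 0` for a noise-free cohort (also silences breath jitter).
#' @return Object of class `group_spec` (a named list).
#' @export
group_spec <- function(group = c("children", "MTA", "WTA"), n = NULL, ...) {
  group <- match.arg(group)
  base <- switch(group,
    children = list(
      n = 18L, n_female = 10L,
      age = c(9.4, 0.9), age_bounds = c(7, 11),
      height = c(139.4, 5.5), body_mass = c(32.3, 3.8), mass_floor = 20,
      vo2peak_rel = c(45.4, 6.6), vo2peak_floor = 25,
      oues_mode = "rel", oues = c(29.5, 8.1), oues_floor = 12,
      ouep = c(39.6, 3.8), ouep_floor = 26,
      vt1_frac = c(0.603, 0.083), vt2_frac = c(0.897, 0.059),
      hr_max = c(197, 6), rer_max = c(1.06, 0.07), rer_floor = 0.95,
      plateau_p = 0.25, vo2_rest_per_kg = 6, hr_rest = 85),
    MTA = list(
      n = 18L, n_female = 8L,
      age = c(25.1, 2.8), age_bounds = c(20, 30),
      height = c(173.5, 9.2), body_mass = c(74.9, 12.2), mass_floor = 45,
      vo2peak_rel = c(41.9, 4.2), vo2peak_floor = 28,
      oues_mode = "abs", oues = c(1140, 190), oues_floor = 500,
      ouep = c(43.5, 5.5), ouep_floor = 28,
      vt1_frac = c(0.595, 0.053), vt2_frac = c(0.909, 0.041),
      hr_max = c(190, 8), rer_max = c(1.21, 0.05), rer_floor = 1.02,
      plateau_p = 0.6, vo2_rest_per_kg = 3.5, hr_rest = 70),
    WTA = list(
      n = 19L, n_female = 8L,
      age = c(24.7, 1.6), age_bounds = c(20, 30),
      height = c(173.8, 10.9), body_mass = c(68.9, 8.2), mass_floor = 45,
      vo2peak_rel = c(50.2, 6.5), vo2peak_floor = 30,
      oues_mode = "abs", oues = c(1560, 380), oues_floor = 600,
      ouep = c(42.4, 3.5), ouep_floor = 28,
      vt1_frac = c(0.542, 0.077), vt2_frac = c(0.871, 0.060),
      hr_max = c(192, 7), rer_max = c(1.21, 0.05), rer_floor = 1.02,
      plateau_p = 0.65, vo2_rest_per_kg = 3.5, hr_rest = 65))
  base$group <- group
  base$noise_sd <- NULL   # NULL = profile defaults
  n0 <- base$n; f0 <- base$n_female
  if (!is.null(n)) base$n <- as.integer(n)
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% c(names(base), "noise_sd")) stop("unknown group_spec field: ", nm)
    base[[nm]] <- dots[[nm]]
  }
  if (base$n != n0 && !"n_female" %in% names(dots)) {
    base$n_female <- as.integer(round(f0 / n0 * base$n))  # keep the sex mix
  }
  for (nm in c("age", "height", "body_mass", "vo2peak_rel", "oues", "ouep",
               "vt1_frac", "vt2_frac", "hr_max", "rer_max")) {
    v <- base[[nm]]
    if (length(v) != 2L) stop("spec field ", nm, " must be c(mean, sd)")
    if (v[2] < 0) stop("degenerate spec: negative SD for ", nm)
  }
  structure(base, class = "group_spec")
}

# truncated-normal draw: mean/sd, truncated at +/- 3 SD and [lo, hi]
.rtnorm <- function(m, s, lo = -Inf, hi = Inf) {
  lo <- max(lo, m - 3 * s); hi <- min(hi, m + 3 * s)
  if (s == 0) return(min(max(m, lo), hi))
  for (k in 1:1000) {
    x <- stats::rnorm(1, m, s)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(m, lo), hi)
}

# stable per-participant sub-seed: counter-based, so a cohort extends
# without reshuffling earlier participants
.sub_seed <- function(seed, i, stream = 0L) {
  (abs(as.integer(seed)) %% 1000003L) * 1009L + i * 7919L +
    stream * 104729L
}

#' Generate a synthetic cohort of ramp tests
#'
#' Samples `n` participants from a [group_spec()] (truncated-normal draws),
#' chooses each ramp protocol via [select_ramp_protocol()] with predicted
#' peak workload `planted VO2peak / vo2_gain`, and simulates every test.
#' Per-participant seeds are derived from `seed` by a counter scheme, so the
#' cohort is reproducible and extensible.
#'
#' @param spec A [group_spec()].
#' @param n Number of participants (default `spec$n`).
#' @param seed Integer master seed.
#' @return List of length `n`; each element has `participant`, `series`
#'   (with ground-truth attribute), `profile` and `protocol`.
#' @export
generate_cohort <- function(spec, n = spec$n, seed = 1) {
  stopifnot(inherits(spec, "group_spec"))
  if (!is.numeric(n) || n <= 0) stop("n must be a positive count")
  n <- as.integer(n)
  lapply(seq_len(n), function(i) {
    set.seed(.sub_seed(seed, i, 0L))
    sex <- if (i <= round(spec$n_female * n / spec$n)) "female" else "male"
    mass <- .rtnorm(spec$body_mass[1], spec$body_mass[2], lo = spec$mass_floor)
    part <- participant(
      id = sprintf("%s%03d", tolower(substr(spec$group, 1, 3)), i),
      group = spec$group, sex = sex,
      age = .rtnorm(spec$age[1], spec$age[2], spec$age_bounds[1],
                    spec$age_bounds[2]),
      body_mass = mass,
      height = .rtnorm(spec$height[1], spec$height[2], lo = 100))
    vt1 <- .rtnorm(spec$vt1_frac[1], spec$vt1_frac[2], 0.35, 0.8)
    vt2 <- .rtnorm(spec$vt2_frac[1], spec$vt2_frac[2], max(0.6, vt1 + 0.05),
                   0.97)
    vt1 <- min(vt1, vt2 - 0.05)
    oues_draw <- .rtnorm(spec$oues[1], spec$oues[2], lo = spec$oues_floor)
    prof_args <- list(
      vo2_rest = spec$vo2_rest_per_kg * mass,
      oues_a = if (spec$oues_mode == "rel") oues_draw * mass else oues_draw,
      vt1_frac = vt1, vt2_frac = vt2,
      vo2peak_rel = .rtnorm(spec$vo2peak_rel[1], spec$vo2peak_rel[2],
                            lo = spec$vo2peak_floor),
      ouep = .rtnorm(spec$ouep[1], spec$ouep[2], lo = spec$ouep_floor),
      hr_max = .rtnorm(spec$hr_max[1], spec$hr_max[2], 150, 220),
      hr_rest = spec$hr_rest,
      rer_max = .rtnorm(spec$rer_max[1], spec$rer_max[2],
                        lo = spec$rer_floor, hi = 1.5),
      plateau = stats::runif(1) < spec$plateau_p,
      plateau_fraction = stats::runif(1, 0.05, 0.45))
    if (!is.null(spec$noise_sd)) {
      ns <- spec$noise_sd
      if (length(ns) == 1L && is.null(names(ns))) {
        ns <- c(vo2 = ns, vco2 = ns, ve = ns, hr = ns / 2,
                peto2 = ns / 4, petco2 = ns / 4)
      }
      prof_args$noise_sd <- ns
      if (all(ns == 0)) prof_args$jitter_sd <- 0
    }
    profile <- do.call(physio_profile, prof_args)
    protocol <- select_ramp_protocol(
      profile$vo2peak_rel * mass / profile$vo2_gain)
    series <- simulate_test(profile, part, protocol,
                            seed = .sub_seed(seed, i, 1L))
    list(participant = part, series = series, profile = profile,
         protocol = protocol)
  })
}

#' Write a cohort to disk as canonical breath CSVs
#'
#' One CSV per participant plus a `manifest.csv` holding the participant
#' metadata and the planted ground truth, so recovery against the planted
#' values is reproducible from the files alone.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(el) {
    p <- el$participant
    path <- file.path(dir, paste0(p$id, ".csv"))
    write_breath_csv(p, el$series, path, protocol = el$protocol)
    tr <- ground_truth(el$series)
    data.frame(id = p$id, group = p$group, sex = p$sex, age = p$age,
               body_mass = p$body_mass, height = p$height,
               file = basename(path),
               planted_vo2peak_rel = tr$vo2peak_rel,
               planted_oues = tr$oues_a, planted_ouep = tr$ouep,
               planted_vo2_vt1_rel = tr$vo2_vt1_rel,
               planted_vo2_vt2_rel = tr$vo2_vt2_rel,
               planted_plateau = tr$plateau)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
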