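#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. The defaults reproduce the
#' reference analysis constants: 30-s smoothing, whole-test OUES scope,
#' automatic threshold detection, 10 mL/min/W expected plateau gain with a
#' 0.5 fraction, RERmax 1.13 (adults) and 95% of 195 bpm (children)
#' exhaustion criteria.
#'
#' @param out_dir Output directory.
#' @param seed Master seed (integer).
#' @param scenario Optional path to a `scenario.yaml` describing the
#'   cohorts: a top-level `groups:` list whose entries carry `group`, `n`,
#'   and any [group_spec()] overrides (`mean`/`sd` pairs given as 2-vectors).
#'   `NULL` uses the three built-in cohorts at their default sizes.
#' @param smooth_window Smoothing window, s (> 0). Default 30.
#' @param oues_scope `"whole"` or `"ramp"`.
#' @param vt_mode `"auto"` or `"manual-import"` (manual mode expects
#'   per-participant times provided via the scenario; only `"auto"` is
#'   meaningful for simulated cohorts).
#' @param plateau_gain,plateau_frac Plateau detector parameters.
#' @param rer_crit,hr_frac,hr_ref Exhaustion parameters.
#' @param alpha Significance level for the comparison report.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, scenario = NULL,
                            smooth_window = 30, oues_scope = "whole",
                            vt_mode = c("auto", "manual-import"),
                            plateau_gain = 10, plateau_frac = 0.5,
                            rer_crit = 1.13, hr_frac = 0.95, hr_ref = 195,
                            alpha = 0.05) {
  if (!is.numeric(smooth_window) || smooth_window <= 0) {
    stop("smooth_window must be a positive number of seconds")
  }
  if (!is.numeric(seed) || length(seed) != 1L) stop("seed must be one integer")
  if (!is.null(scenario) && !file.exists(scenario)) {
    stop("scenario file not found: ", scenario)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 scenario = scenario, smooth_window = smooth_window,
                 oues_scope = match.arg(oues_scope, c("whole", "ramp")),
                 vt_mode = match.arg(vt_mode),
                 plateau_gain = plateau_gain, plateau_frac = plateau_frac,
                 rer_crit = rer_crit, hr_frac = hr_frac, hr_ref = hr_ref,
                 alpha = alpha),
            class = "pipeline_config")
}

.load_scenario <- function(config) {
  if (is.null(config$scenario)) {
    return(list(group_spec("children"), group_spec("MTA"), group_spec("WTA")))
  }
  sc <- yaml::read_yaml(config$scenario)
  if (is.null(sc$groups)) stop("scenario.yaml needs a top-level 'groups:' list")
  lapply(sc$groups, function(gs) {
    args <- gs
    # YAML 1.1 reads a bare `n:` key as the boolean FALSE; map it back
    names(args)[names(args) %in% c("FALSE", "no")] <- "n"
    args$group <- NULL
    for (nm in names(args)) {
      if (is.list(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
    }
    do.call(group_spec, c(list(group = gs$group), args))
  })
}

#' Run the full generate - summarise - compare pipeline
#'
#' Generates the configured cohorts, writes each test as a canonical breath
#' CSV (plus `manifest.csv`), summarises every participant, and writes
#' `summaries.csv`, `descriptives.csv`, `comparisons.csv`,
#' `comparisons.json` and a `provenance.json` recording every parameter and
#' seed, which suffices to re-run bit-identically. A participant whose
#' summary fails is skipped with a warning; the pipeline continues and
#' errors only if a whole stage produces nothing.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `summaries` (data frame), `comparisons`,
#'   `descriptives` and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- .load_scenario(config)

  rows <- list(); summaries <- list()
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    cohort <- generate_cohort(spec, seed = .sub_seed(config$seed, k, 2L))
    write_cohort(cohort, file.path(config$out_dir, "cohorts", spec$group))
    for (el in cohort) {
      res <- tryCatch({
        qc <- qc_screen(el$series)
        if (!qc$usable) stop("failed QC screen")
        summarize_test(el$participant, el$series, el$protocol,
                       smooth_window = config$smooth_window,
                       oues_scope = config$oues_scope)
      }, error = function(e) {
        warning("participant ", el$participant$id, " skipped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (!is.null(res)) {
        summaries[[length(summaries) + 1L]] <- res
        rows[[length(rows) + 1L]] <- as.data.frame(res)
      }
    }
  }
  if (length(summaries) == 0L) stop("summarise stage produced no usable tests")
  sum_df <- do.call(rbind, rows)
  desc <- descriptive_table(summaries)
  comp <- compare_groups(summaries, alpha = config$alpha)

  paths <- list(
    summaries = file.path(config$out_dir, "summaries.csv"),
    descriptives = file.path(config$out_dir, "descriptives.csv"),
    comparisons = file.path(config$out_dir, "comparisons.csv"),
    comparisons_json = file.path(config$out_dir, "comparisons.json"),
    provenance = file.path(config$out_dir, "provenance.json"))
  utils::write.csv(sum_df, paths$summaries, row.names = FALSE)
  utils::write.csv(desc, paths$descriptives, row.names = FALSE)
  utils::write.csv(comp, paths$comparisons, row.names = FALSE)
  jsonlite::write_json(comp, paths$comparisons_json, dataframe = "rows",
                       digits = NA, auto_unbox = TRUE)
  prov <- c(unclass(config),
            list(package_version = as.character(utils::packageVersion("cpetr")),
                 n_summaries = length(summaries),
                 note = "no multiple-testing correction applied"))
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(list(summaries = sum_df, descriptives = desc, comparisons = comp,
                 paths = paths))
}

#' Miniature deterministic test corpus
#'
#' Writes three noise-free tests (one participant per cohort) as canonical
#' breath CSVs plus a manifest. Regenerating with the same seed reproduces
#' the files byte for byte; the unit tests rely on this corpus instead of
#' committed fixtures.
#'
#' @param dir Output directory.
#' @param seed Integer seed. Default 7.
#' @return Invisibly, the manifest data frame.
#' @export
make_fixtures <- function(dir, seed = 7) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (g in c("children", "MTA", "WTA")) {
    spec <- group_spec(g, noise_sd = 0)
    cohort <- generate_cohort(spec, n = 1, seed = seed)
    rows[[g]] <- write_cohort(cohort, dir)
    file.rename(file.path(dir, "manifest.csv"),
                file.path(dir, paste0("manifest_", g, ".csv")))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
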