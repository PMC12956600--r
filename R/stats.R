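# The 13 outcome columns analysed at cohort level, in report order.
.outcome_cols <- c(
  "vo2_vt1_rel_ml_kg_min", "vo2_vt2_rel_ml_kg_min",
  "vt1_over_vo2peak_pct", "vt2_over_vo2peak_pct",
  "oues_l_min", "oues_rel_ml_min_kg",
  "ouep_ml_l", "ouep_over_vo2peak_pct",
  "oue_vt1_ml_l", "oue_vt2_ml_l",
  "o2_per_watt_ml_min_w",
  "p_vt1_over_ppeak_pct", "p_vt2_over_ppeak_pct")

# Outcomes that depend on a valid maximal effort (peak-referenced ratios);
# participants failing the exhaustion criterion contribute only to the
# submaximal outcomes.
.maximal_cols <- c("vt1_over_vo2peak_pct", "vt2_over_vo2peak_pct",
                   "ouep_over_vo2peak_pct",
                   "p_vt1_over_ppeak_pct", "p_vt2_over_ppeak_pct")

#' Build the participant-by-outcome matrix
#'
#' One row per participant, the 13 analysis outcomes as columns, plus the
#' `group` and `sex` covariates and the maximal-inclusion flag.
#' Peak-referenced outcomes are blanked (`NA`) for participants with
#' `include_maximal = FALSE`, implementing the rule that non-exhausted
#' participants enter only the submaximal analyses.
#'
#' @param summaries List of [summarize_test()] results (or an already-flat
#'   data frame of their rows).
#' @return Data frame of class `outcome_matrix`.
#' @export
outcome_matrix <- function(summaries) {
  df <- if (is.data.frame(summaries)) summaries else
    do.call(rbind, lapply(summaries, as.data.frame))
  need <- c("id", "group", "sex", "include_maximal", .outcome_cols)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("summaries lack columns: ", paste(miss, collapse = ", "))
  out <- df[, need]
  for (col in .maximal_cols) out[[col]][!out$include_maximal] <- NA_real_
  out$group <- factor(out$group, levels = c("children", "MTA", "WTA"))
  out$sex <- factor(out$sex, levels = c("female", "male"))
  class(out) <- c("outcome_matrix", "data.frame")
  out
}

#' Names of the 13 cohort outcomes
#' @return Character vector of outcome column names.
#' @export
outcome_names <- function() .outcome_cols

#' Descriptive mean (SD) table
#'
#' Mean and sample SD (n-1) per group x sex cell, formatted `"x.x (y.y)"`;
#' empty cells render as an en dash and single-participant cells carry SD
#' 0.0 with a degenerate-cell warning.
#'
#' @param summaries As for [outcome_matrix()].
#' @param digits Decimal places. Default 1.
#' @return Data frame with one row per outcome and one column per
#'   group/sex cell (both-sexes, female, male for each group).
#' @export
descriptive_table <- function(summaries, digits = 1) {
  m <- outcome_matrix(summaries)
  cells <- list()
  for (g in levels(m$group)) {
    for (s in c("both", "female", "male")) {
      keep <- m$group == g & (s == "both" | m$sex == s)
      cells[[paste(g, s, sep = ".")]] <- vapply(.outcome_cols, function(col) {
        v <- m[[col]][keep]
        v <- v[!is.na(v)]
        if (length(v) == 0L) return("–")
        if (length(v) == 1L) {
          warning("degenerate cell (n=1): ", g, "/", s, "/", col, call. = FALSE)
          return(sprintf(paste0("%.", digits, "f (0.", strrep("0", digits), ")"), v))
        }
        sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
                mean(v), stats::sd(v))
      }, character(1))
    }
  }
  out <- data.frame(outcome = .outcome_cols, cells, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Linear model for group differences with sex as covariate
#'
#' OLS of one outcome on indicator-coded sex and group (reference levels:
#' female, children), so the group coefficients read directly as the
#' MTA-children / WTA-children contrasts and the sex coefficient as
#' male-female. Returns Wald confidence intervals using t critical values
#' at the residual degrees of freedom and two-sided p-values.
#'
#' @param matrix An [outcome_matrix()].
#' @param outcome One of [outcome_names()].
#' @param conf_level Confidence level. Default 0.95.
#' @return Data frame: one row per non-intercept coefficient with `term`,
#'   `contrast`, `estimate`, `se`, `ci_lo`, `ci_hi`, `p`, `df`, `n`.
#' @export
fit_group_model <- function(matrix, outcome, conf_level = 0.95) {
  stopifnot(inherits(matrix, "outcome_matrix"))
  if (!outcome %in% names(matrix)) stop("unknown outcome: ", outcome)
  d <- matrix[!is.na(matrix[[outcome]]), , drop = FALSE]
  d$group <- droplevels(d$group)
  if (nlevels(d$group) < 2L) stop("need at least two groups with data")
  terms <- c("sex", "group")
  if (nlevels(droplevels(d$sex)) < 2L) terms <- "group"  # single-sex data
  fit <- stats::lm(stats::reformulate(terms, response = outcome), data = d)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design; collinear columns: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  df <- fit$df.residual
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  contrast_of <- c(sexmale = "male-female", groupMTA = "MTA-children",
                   groupWTA = "WTA-children")
  data.frame(
    term = rownames(sm),
    contrast = unname(contrast_of[rownames(sm)]),
    estimate = sm[, 1], se = sm[, 2],
    ci_lo = sm[, 1] - tcrit * sm[, 2], ci_hi = sm[, 1] + tcrit * sm[, 2],
    p = sm[, 4], df = df, n = nrow(d), row.names = NULL)
}

#' Cohen's d for a pairwise contrast
#'
#' Standardised mean difference from the raw group means with the pooled
#' sample SD, `d = (mean_A - mean_B) / s_p`,
#' `s_p = sqrt(((n_A-1) s_A^2 + (n_B-1) s_B^2) / (n_A+n_B-2))`; the sign
#' follows the stated contrast order. A model-based alternative (adjusted
#' coefficient divided by residual SD) is available via `method`.
#'
#' @param matrix An [outcome_matrix()].
#' @param outcome One of [outcome_names()].
#' @param contrast Length-2 character: levels of `group` (or of `sex`) as
#'   (A, B) for A - B, e.g. `c("MTA", "children")` or `c("male", "female")`.
#' @param method `"pooled"` (default) or `"model"`.
#' @return Cohen's d (NaN with a warning when the pooled SD is zero).
#' @export
cohens_d <- function(matrix, outcome, contrast, method = c("pooled", "model")) {
  stopifnot(inherits(matrix, "outcome_matrix"), length(contrast) == 2L)
  method <- match.arg(method)
  var_name <- if (all(contrast %in% levels(matrix$sex))) "sex" else "group"
  v <- matrix[[outcome]]
  a <- v[matrix[[var_name]] == contrast[1] & !is.na(v)]
  b <- v[matrix[[var_name]] == contrast[2] & !is.na(v)]
  if (length(a) == 0L || length(b) == 0L) stop("empty contrast group")
  if (method == "model") {
    fit <- stats::lm(stats::reformulate(c("sex", "group"), response = outcome),
                     data = matrix[!is.na(v), ])
    term <- if (var_name == "sex") paste0("sex", contrast[1]) else
      paste0("group", setdiff(contrast, "children"))
    return(unname(stats::coef(fit)[term]) *
             (if (contrast[2] %in% c("children", "female")) 1 else -1) /
             summary(fit)$sigma)
  }
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) {
    warning("zero pooled SD: Cohen's d undefined")
    return(NaN)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Effect-size band of a Cohen's d
#'
#' On |d|: `[0, 0.2)` negligible, `[0.2, 0.5)` small, `[0.5, 0.8)` medium,
#' `[0.8, Inf)` large. The interval edges in the source convention overlap
#' (0.2-0.5 small, 0.5-0.8 medium); the half-open-to-the-right reading used
#' here assigns each boundary to the higher band.
#'
#' @param d Numeric vector of Cohen's d values (finite).
#' @return Character vector of band labels.
#' @export
classify_effect <- function(d) {
  if (any(!is.finite(d))) stop("d must be finite")
  as.character(cut(abs(d), breaks = c(0, 0.2, 0.5, 0.8, Inf), right = FALSE,
                   labels = c("negligible", "small", "medium", "large")))
}

#' Cohort comparison report
#'
#' Builds the outcome matrix, fits the sex-and-group linear model per
#' outcome, and attaches Cohen's d with its band label for every contrast
#' (MTA-children, WTA-children, male-female). Outcomes whose column is
#' entirely missing are skipped with a warning. No multiple-testing
#' correction is applied.
#'
#' @param summaries As for [outcome_matrix()].
#' @param alpha Significance level for the `significant` flag. Default 0.05.
#' @return Data frame of class `group_comparison`: one row per outcome x
#'   contrast with estimate, SE, CI, p, Cohen's d and band.
#' @export
compare_groups <- function(summaries, alpha = 0.05) {
  m <- outcome_matrix(summaries)
  rows <- list()
  for (col in .outcome_cols) {
    if (all(is.na(m[[col]]))) {
      warning("outcome entirely missing, skipped: ", col, call. = FALSE)
      next
    }
    fit <- fit_group_model(m, col)
    for (k in seq_len(nrow(fit))) {
      ct <- strsplit(fit$contrast[k], "-", fixed = TRUE)[[1]]
      d <- cohens_d(m, col, ct)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = col, contrast = fit$contrast[k],
        estimate = fit$estimate[k], se = fit$se[k],
        ci_lo = fit$ci_lo[k], ci_hi = fit$ci_hi[k], p = fit$p[k],
        significant = fit$p[k] < alpha,
        cohens_d = d,
        band = if (is.finite(d)) classify_effect(d) else NA_character_,
        n = fit$n[k])
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_comparison", "data.frame")
  out
}
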