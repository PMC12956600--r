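# A small synthetic summary table; building it as a data frame exercises the
# data-frame entry path of outcome_matrix().
fake_rows <- function(n_per_group = 8, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(group = c("children", "MTA", "WTA"),
                      i = seq_len(n_per_group))
  n <- nrow(grid)
  df <- data.frame(
    id = sprintf("s%02d", seq_len(n)),
    group = as.character(grid$group),
    sex = rep_len(c("female", "male"), n),
    include_maximal = TRUE)
  for (col in outcome_names()) df[[col]] <- rnorm(n, 40, 5)
  df
}

test_that("group model equals the hand-solved normal equations", {
  df <- fake_rows()
  m <- outcome_matrix(df)
  out <- fit_group_model(m, "oues_l_min")
  X <- cbind(1, as.integer(m$sex == "male"), as.integer(m$group == "MTA"),
             as.integer(m$group == "WTA"))
  y <- m$oues_l_min
  beta <- solve(t(X) %*% X, t(X) %*% y)[, 1]
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(sigma2 * solve(t(X) %*% X)))
  expect_equal(out$estimate, beta[2:4], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(out$se, se[2:4], tolerance = 1e-9, ignore_attr = TRUE)
  tcrit <- qt(0.975, nrow(X) - ncol(X))
  expect_equal(out$ci_lo, out$estimate - tcrit * out$se)
  p_want <- 2 * pt(-abs(beta[2:4] / se[2:4]), nrow(X) - ncol(X))
  expect_equal(out$p, p_want, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("permuted labels give a near-zero group coefficient on average", {
  df <- fake_rows(n_per_group = 12, seed = 3)
  ests <- replicate(60, {
    df$group <- sample(df$group)
    fit_group_model(outcome_matrix(df), "ouep_ml_l")$estimate[2]
  })
  expect_lt(abs(mean(ests)), 2 * sd(ests) / sqrt(60) * 3)
})

test_that("Cohen's d follows the pooled-SD arithmetic and is antisymmetric", {
  df <- fake_rows()
  keep <- df$group %in% c("children", "MTA")
  df$oues_l_min[df$group == "children"] <- rep(c(8, 10, 12), length.out = 8)
  df$oues_l_min[df$group == "MTA"] <- rep(c(6, 8, 10), length.out = 8)
  m <- outcome_matrix(df)
  d <- cohens_d(m, "oues_l_min", c("children", "MTA"))
  a <- m$oues_l_min[m$group == "children"]; b <- m$oues_l_min[m$group == "MTA"]
  sp <- sqrt(((7) * var(a) + (7) * var(b)) / 14)
  expect_equal(d, (mean(a) - mean(b)) / sp)
  expect_equal(cohens_d(m, "oues_l_min", c("MTA", "children")), -d)

  # hand case: means 10 and 8, both SD exactly 2, equal n -> d = 1
  df2 <- fake_rows(n_per_group = 2)
  df2$ouep_ml_l[df2$group == "children"] <- c(8, 12)    # mean 10, sd 2.83
  df2$ouep_ml_l[df2$group == "MTA"] <- c(6, 10)
  m2 <- outcome_matrix(df2)
  expect_equal(cohens_d(m2, "ouep_ml_l", c("children", "MTA")),
               2 / sqrt(8))
  df2$ouep_ml_l[df2$group == "MTA"] <- c(8, 12)          # equal distributions
  expect_equal(cohens_d(outcome_matrix(df2), "ouep_ml_l",
                        c("children", "MTA")), 0)
  df2$ouep_ml_l <- 5                                     # zero pooled SD
  expect_warning(
    dd <- cohens_d(outcome_matrix(df2), "ouep_ml_l", c("children", "MTA")),
    "pooled SD")
  expect_true(is.nan(dd))
})

test_that("effect bands use half-open intervals on |d|", {
  expect_identical(classify_effect(0.35), "small")
  expect_identical(classify_effect(-0.9), "large")
  expect_identical(classify_effect(0.5), "medium")   # boundary to upper band
  expect_identical(classify_effect(0.2), "small")
  expect_identical(classify_effect(0.8), "large")
  expect_identical(classify_effect(0.19), "negligible")
  expect_error(classify_effect(Inf), "finite")
  # monotone and total over a sweep
  d <- seq(-2, 2, by = 0.01)
  bands <- classify_effect(d)
  lev <- c(negligible = 1, small = 2, medium = 3, large = 4)
  expect_true(all(!is.na(bands)))
  expect_true(all(diff(lev[bands[d >= 0]]) >= 0))
})

test_that("non-exhausted participants enter only the submaximal outcomes", {
  df <- fake_rows()
  df$include_maximal[df$id %in% c("s01", "s05")] <- FALSE
  m <- outcome_matrix(df)
  expect_true(all(is.na(m$vt2_over_vo2peak_pct[!m$include_maximal])))
  expect_false(anyNA(m$oues_l_min))
  # dropping a non-exhausted participant leaves submaximal-row n unchanged
  fit_all <- fit_group_model(m, "vt2_over_vo2peak_pct")
  expect_equal(unique(fit_all$n), sum(df$include_maximal))
  fit_sub <- fit_group_model(m, "oues_l_min")
  expect_equal(unique(fit_sub$n), nrow(df))
})

test_that("comparison report has outcomes x contrasts rows with bands", {
  df <- fake_rows()
  comp <- compare_groups(df)
  expect_equal(nrow(comp), length(outcome_names()) * 3L)
  expect_setequal(unique(comp$contrast),
                  c("male-female", "MTA-children", "WTA-children"))
  expect_true(all(comp$band %in% c("negligible", "small", "medium", "large")))
  expect_identical(comp$significant, comp$p < 0.05)
  # an all-missing outcome is skipped with a warning
  df2 <- df; df2$o2_per_watt_ml_min_w <- NA_real_
  expect_warning(comp2 <- compare_groups(df2), "o2_per_watt")
  expect_equal(nrow(comp2), (length(outcome_names()) - 1L) * 3L)
})

test_that("descriptive cells are formatted as mean (sample SD)", {
  df <- fake_rows()
  df$ouep_ml_l[df$group == "children" & df$sex == "female"] <-
    rep(c(40, 44), 2)
  tab <- suppressWarnings(descriptive_table(df))
  row <- tab[tab$outcome == "ouep_ml_l", ]
  expect_identical(row[["children.female"]], "42.0 (2.3)")  # n-1 SD of 40,44,40,44
  two <- df[df$id %in% c("s01", "s04"), ]   # one female child, one male child
  two$ouep_ml_l <- c(40, 44)
  w <- capture_warnings(tab2 <- descriptive_table(two))
  expect_true(any(grepl("degenerate", w)))
  r2 <- tab2[tab2$outcome == "ouep_ml_l", ]
  expect_identical(r2[["children.both"]], "42.0 (2.8)")     # sd(c(40,44)) = 2.83
  expect_identical(r2[["children.female"]], "40.0 (0.0)")
  expect_identical(r2[["MTA.both"]], "–")
})
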