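test_that("group comparison routes tests and matches rank/contingency oracles", {
  # identical samples: no location shift, Mann-Whitney p ~ 1
  cmp <- compare_groups(list(c(1, 2, 3, 10, 20), c(1, 2, 3, 10, 20)),
                        "continuous", test = "mann_whitney")
  expect_gt(cmp$p, 0.9)

  # fully separated ranks: U = 0 by exhaustive rank enumeration
  g1 <- c(1, 2, 3)
  g2 <- c(4, 5, 6)
  u_oracle <- sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  cmp <- compare_groups(list(g1, g2), "continuous", test = "mann_whitney")
  expect_equal(cmp$test, "mann_whitney")
  expect_equal(cmp$statistic, u_oracle)

  # chi-square without continuity correction matches the closed form
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  chi_oracle <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  cmp <- compare_groups(tab, "categorical")
  expect_equal(cmp$test, "chi_square")
  expect_equal(cmp$statistic, chi_oracle)

  # small expected counts fall back to the exact test
  cmp <- compare_groups(matrix(c(3, 1, 0, 4), 2, 2), "categorical")
  expect_equal(cmp$test, "fisher_exact")

  # normal samples route to the t-test
  set.seed(1)
  cmp <- compare_groups(list(rnorm(30), rnorm(30, 1)), "continuous")
  expect_equal(cmp$test, "t")

  expect_error(compare_groups(list(1, 1:5), "continuous"), "n >= 2")
})

test_that("Cohen's d uses the pooled n-1 standard deviation", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohens_d(c(0, 0, 0, 0), c(1, 1, 1, 1)), "pooled variance")
  x <- c(1, 2, 3); y <- c(3, 4, 5)
  sp <- sqrt((2 * var(x) + 2 * var(y)) / 4)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp)
  expect_equal(cohens_d(x, y), -2)  # hand value: diff -2, pooled sd 1
})

test_that("covariate-adjusted contrast flags collinearity and separation", {
  md <- toy_metadata(n_good = 30, n_poor = 30, seed = 5)
  covars <- md[, c("arrest_to_mri_h", "hospital", "comatose")]

  # metric duplicating a covariate: rank-deficient design
  expect_error(
    adjusted_group_difference(md$arrest_to_mri_h, md$outcome, covars),
    "collinear")

  # metric equal to the outcome indicator: separation diagnostic
  y <- as.integer(md$outcome == "poor")
  expect_error(adjusted_group_difference(y, md$outcome, covars),
               "separation")

  # a well-behaved metric returns a finite Wald p
  set.seed(6)
  res <- adjusted_group_difference(rnorm(60), md$outcome, covars)
  expect_true(is.finite(res$p) && res$p >= 0 && res$p <= 1)
})

test_that("adjusted logistic contrast detects a strong simulated effect", {
  hits <- 0
  for (s in 1:20) {
    # milder comatose linkage than the cohort default: at this n the
    # default (0.96 in poor outcome) quasi-separates the model on its
    # own, which is a diagnostic path tested elsewhere
    cfg <- cohort_config(n_good = 44, n_poor = 26, n_nodes = 12,
                         n_volumes = 80, n_modules = 4,
                         coupling_good = 0.85, coupling_poor = 0.5,
                         comatose_prob = c(good = 0.35, poor = 0.75),
                         seed = 500 + s)
    co <- generate_cohort(cfg)
    fc <- vapply(co$subjects, function(x)
      whole_brain_fc(subject_connectivity(x$timeseries)), numeric(1))
    md <- co$metadata
    p <- tryCatch(
      adjusted_group_difference(fc, md$outcome,
        md[, c("arrest_to_mri_h", "hospital", "comatose")])$p,
      error = function(e) NA_real_)
    if (!is.na(p) && p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 16)  # strong coupling contrast: high power expected
})

test_that("FDR adjustment reproduces the BH step-up", {
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(2)
  p <- runif(25)
  expect_true(all(fdr_adjust(p) >= p))
  # adjustment preserves the ordering of the raw p values
  expect_true(all(diff(fdr_adjust(sort(p))) >= 0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("nodewise outcome correlation handles perfect and degenerate nodes", {
  outcomes <- rep(c("good", "poor"), c(6, 6))
  y <- as.integer(outcomes == "good")
  set.seed(3)
  nodewise <- cbind(y,                       # identical to the indicator
                    rep(0.5, 12),            # constant: undefined r
                    rnorm(12))
  res <- nodewise_outcome_correlation(nodewise, outcomes)
  expect_equal(res$results$r[1], 1)
  expect_true(is.na(res$results$r[2]))
  expect_equal(nrow(res$results), 3)
  # the constant node is excluded from the threshold counts
  expect_lte(res$counts[["p05"]], 2)
})

test_that("EEG-category tests gate pairwise contrasts on the omnibus", {
  set.seed(4)
  vals <- c(rnorm(10), rnorm(10), rnorm(10, 8))
  cats <- rep(c("continuous", "suppressed", "epileptiform"), each = 10)
  res <- eeg_category_tests(vals, cats)
  expect_lt(res$omnibus$p, 0.05)
  expect_false(is.null(res$pairwise))
  # the shifted category differs from both others after FDR
  sig <- res$pairwise[res$pairwise$cat1 == "epileptiform" |
                        res$pairwise$cat2 == "epileptiform", ]
  expect_true(all(sig$p_fdr < 0.05))
  # the two identical categories do not differ
  same <- res$pairwise[res$pairwise$cat1 == "continuous" &
                         res$pairwise$cat2 == "suppressed", ]
  expect_gt(same$p_raw, 0.05)

  # omnibus failure suppresses the pairwise stage
  set.seed(5)
  res0 <- eeg_category_tests(rnorm(30),
                             rep(c("a", "b", "c"), each = 10))
  if (res0$omnibus$p >= 0.05) expect_null(res0$pairwise)

  # undersized categories are dropped with a warning
  expect_warning(
    eeg_category_tests(c(rnorm(10), rnorm(10), 1),
                       c(rep("a", 10), rep("b", 10), "tiny")),
    "n < 2")
})

test_that("metric correlations match the direct Pearson formula", {
  set.seed(6)
  fc <- rnorm(5)
  tab <- data.frame(FC = fc, C = 2 * fc, GE = rnorm(5), Q = rnorm(5))
  mc <- metric_correlations(tab)
  expect_equal(mc$r["FC", "FC"], 1)
  expect_equal(mc$r["FC", "C"], 1)       # exact linearity
  expect_equal(mc$r["FC", "GE"], oracle_pearson(tab$FC, tab$GE))
  expect_equal(mc$r["GE", "Q"], oracle_pearson(tab$GE, tab$Q))
  expect_true(isSymmetric(mc$r))
  # constant column yields missing entries
  tab$Q <- 1
  mc <- metric_correlations(tab)
  expect_true(all(is.na(mc$r["Q", c("FC", "C", "GE")])))
})
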