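test_that("intercept-only model fits the empirical event rate", {
  md <- toy_metadata(n_good = 44, n_poor = 26)
  fit <- fit_guideline_model(md, predictors = character(0))
  expect_equal(unname(fit$fitted), rep(26 / 70, 70))
  # log-likelihood equals the independent per-subject Bernoulli sum
  y <- as.integer(md$outcome == "poor")
  expect_equal(fit$loglik, sum(dbinom(y, 1, 26 / 70, log = TRUE)))
})

test_that("guideline fit matches glm and the Bernoulli likelihood oracle", {
  md <- toy_metadata(n_good = 44, n_poor = 26, seed = 5)
  fit <- fit_guideline_model(md)
  y <- as.integer(md$outcome == "poor")
  ref <- glm(y ~ pupils_ssep_absent +
               factor(eeg_guideline, c("indifferent", "good", "poor")),
             data = md, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(fit$loglik, sum(dbinom(y, 1, fit$fitted, log = TRUE)))
  expect_false(fit$penalized)
})

test_that("augmentation preserves nesting and reacts to the metric", {
  md <- toy_metadata(n_good = 30, n_poor = 20, seed = 9)
  guide <- fit_guideline_model(md)

  # constant metric adds no information
  aug0 <- augment_model(md, rep(1.7, 50), metric_name = "const")
  expect_equal(aug0$loglik, guide$loglik, tolerance = 1e-6)

  # metric equal to the outcome indicator triggers the separation fallback
  y <- as.integer(md$outcome == "poor")
  expect_warning(sep_fit <- augment_model(md, y, metric_name = "leak"),
                 "separation")
  expect_true(sep_fit$penalized)

  # an informative simulated metric strictly increases the log-likelihood
  set.seed(10)
  metric <- y + rnorm(50, sd = 0.8)
  aug <- augment_model(md, metric)
  expect_gt(aug$loglik, guide$loglik)
})

test_that("ROC analysis reproduces the rank-statistic identity", {
  roc <- roc_analysis(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(roc$auc, 1)
  roc <- roc_analysis(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(roc$auc, 0.5)

  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(0, 0, 1, 1)
  u <- sum(outer(scores[labels == 1], scores[labels == 0], ">")) +
    0.5 * sum(outer(scores[labels == 1], scores[labels == 0], "=="))
  expect_equal(roc_analysis(scores, labels)$auc, u / 4)

  # random instances, including ties, against the Mann-Whitney identity
  set.seed(11)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    u <- sum(outer(sc[lb == 1], sc[lb == 0], ">")) +
      0.5 * sum(outer(sc[lb == 1], sc[lb == 0], "=="))
    expect_equal(roc_analysis(sc, lb)$auc,
                 u / (sum(lb == 1) * sum(lb == 0)), tolerance = 1e-12)
  }

  expect_error(roc_analysis(c(0.2, 0.4), c(1, 1)), "both classes")
})

test_that("ROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  sc <- rnorm(40)
  lb <- rbinom(40, 1, 0.5)
  expect_equal(roc_analysis(sc, lb)$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("sensitivity at constrained specificity enumerates cut points", {
  perfect <- roc_analysis(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sensitivity_at_specificity(perfect, 0.90), 1)
  expect_equal(sensitivity_at_specificity(perfect, 1.00), 1)

  # constant scores: only the degenerate all-negative point qualifies
  flat <- roc_analysis(rep(0.3, 8), c(1, 1, 1, 0, 0, 0, 0, 1))
  expect_equal(sensitivity_at_specificity(flat, 1.00), 0)

  # 4-subject toy against brute-force enumeration of every threshold
  sc <- c(0.2, 0.6, 0.5, 0.9)
  lb <- c(0, 0, 1, 1)
  roc <- roc_analysis(sc, lb)
  for (ms in c(0.5, 0.9, 1.0)) {
    brute <- 0
    for (t in c(sort(unique(sc)), Inf)) {
      spec <- sum(sc < t & lb == 0) / sum(lb == 0)
      sens <- sum(sc >= t & lb == 1) / sum(lb == 1)
      if (spec >= ms) brute <- max(brute, sens)
    }
    expect_equal(sensitivity_at_specificity(roc, ms), brute)
  }
})

test_that("likelihood-ratio test matches the chi-square oracle", {
  md <- toy_metadata(n_good = 30, n_poor = 20, seed = 3)
  guide <- fit_guideline_model(md)
  lrt <- likelihood_ratio_test(guide, guide)
  expect_equal(lrt$statistic, 0)
  expect_equal(lrt$p, 1)

  # fixed log-likelihood difference against the distribution function
  nested <- guide
  full <- guide
  full$loglik <- nested$loglik + 1.92
  full$df <- nested$df + 1L
  lrt <- likelihood_ratio_test(nested, full)
  expect_equal(lrt$statistic, 3.84)
  expect_equal(lrt$p, pchisq(3.84, 1, lower.tail = FALSE))
  expect_equal(lrt$p, 0.05, tolerance = 0.001)

  # a full model with lower likelihood signals a fitting failure
  bad <- guide
  bad$loglik <- guide$loglik - 0.5
  bad$df <- guide$df + 1L
  expect_error(likelihood_ratio_test(guide, bad), "fitting failure")
})

test_that("adding predictors never decreases the log-likelihood", {
  set.seed(14)
  for (i in 1:10) {
    md <- toy_metadata(n_good = 25, n_poor = 15, seed = 100 + i)
    guide <- suppressWarnings(fit_guideline_model(md))
    aug <- suppressWarnings(augment_model(md, rnorm(40)))
    if (guide$penalized || aug$penalized) next
    expect_gte(aug$loglik, guide$loglik - 1e-8)
  }
})

test_that("model comparison table covers guideline, single and augmented models", {
  md <- toy_metadata(n_good = 40, n_poor = 25, seed = 16)
  set.seed(16)
  y <- as.integer(md$outcome == "poor")
  metrics <- data.frame(
    whole_brain_fc = -0.5 * y + rnorm(65, sd = 1.5),
    clustering_auc = -0.5 * y + rnorm(65, sd = 1.5),
    global_efficiency_auc = rnorm(65),
    modularity_auc = rnorm(65)
  )
  cmp <- suppressWarnings(compare_prediction_models(md, metrics))
  expect_equal(nrow(cmp), 9)  # guideline + 4 x (alone, augmented)
  expect_true(all(cmp$auc >= 0 & cmp$auc <= 1))
  expect_true(all(cmp$sens_good >= 0 & cmp$sens_good <= 1))
  expect_true(all(cmp$sens_poor >= 0 & cmp$sens_poor <= 1))
  aug_rows <- grepl("^guideline\\+", cmp$model_label)
  expect_true(all(is.finite(cmp$lrt_p[aug_rows])))
  expect_true(all(is.na(cmp$lrt_p[!aug_rows])))
})
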