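#' Guideline-based prognostic logistic model
#'
#' Maximum-likelihood logistic regression of poor outcome (the modelled
#' event) on the established guideline predictors: the combined
#' bilateral-fixed-pupils / absent-SSEPs indicator and the guideline EEG
#' class (good / poor / indifferent, entered as two treatment contrasts
#' against `indifferent`). When the fit (quasi-)separates, a
#' ridge-penalized logistic fit with penalty `penalty` on the
#' non-intercept coefficients is used instead, with a warning; the
#' reported log-likelihood is always the unpenalized likelihood at the
#' returned coefficients.
#'
#' @param metadata Data frame with columns `outcome` (good/poor),
#'   `pupils_ssep_absent` (logical) and `eeg_guideline`
#'   (good/poor/indifferent), one row per subject.
#' @param predictors Character vector of metadata columns to use; the
#'   default is the guideline set. `character(0)` fits an intercept-only
#'   model.
#' @param penalty Ridge penalty used only in the separation fallback.
#' @param label Model label carried into results tables.
#' @return Object of class `comanet_logit`: `coefficients`, `fitted`
#'   (probability of poor outcome per subject), `loglik`, `df` (number of
#'   coefficients), `penalized` flag, `label`, and the model `data`.
#' @export
fit_guideline_model <- function(metadata,
                                predictors = c("pupils_ssep_absent",
                                               "eeg_guideline"),
                                penalty = 0.5, label = "guideline") {
  y <- outcome_indicator(metadata$outcome, positive = "poor")
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  df <- prepare_predictors(metadata, predictors)
  X <- if (ncol(df) == 0)
    matrix(1, nrow(metadata), 1, dimnames = list(NULL, "(Intercept)"))
  else model.matrix(~ ., data = df)
  fit_logistic(X, y, penalty = penalty, label = label)
}

#' Augment the guideline model with a graph measure
#'
#' Refits the guideline model with one graph-measure column appended, so
#' the guideline model stays nested inside the augmented one for the
#' likelihood-ratio test.
#'
#' @inheritParams fit_guideline_model
#' @param metric Numeric vector, one value per subject.
#' @param metric_name Name used for the added coefficient and the label.
#' @return A `comanet_logit` (see [fit_guideline_model()]).
#' @export
augment_model <- function(metadata, metric, metric_name = "metric",
                          predictors = c("pupils_ssep_absent",
                                         "eeg_guideline"),
                          penalty = 0.5) {
  y <- outcome_indicator(metadata$outcome, positive = "poor")
  if (length(metric) != nrow(metadata))
    stop("metric must have one value per subject")
  df <- prepare_predictors(metadata, predictors)
  df[[metric_name]] <- metric
  X <- model.matrix(~ ., data = df)
  fit_logistic(X, y, penalty = penalty,
               label = paste0("guideline+", metric_name))
}

prepare_predictors <- function(metadata, predictors) {
  df <- metadata[, predictors, drop = FALSE]
  if ("eeg_guideline" %in% predictors) {
    lev <- c("indifferent", "good", "poor")
    bad <- setdiff(unique(as.character(df$eeg_guideline)), lev)
    if (length(bad) > 0)
      stop("eeg_guideline must be good/poor/indifferent; found: ",
           paste(bad, collapse = ", "))
    df$eeg_guideline <- factor(df$eeg_guideline, levels = lev)
  }
  df
}

# (quasi-)separation heuristic: any coefficient beyond `cut` logits per
# predictor standard deviation (no plausible effect is that large), or a
# fitted probability numerically at 0/1
detect_separation <- function(X, beta, fitted, cut = 15) {
  sds <- apply(X, 2, sd)
  std <- abs(beta[sds > 0]) * sds[sds > 0]
  (length(std) > 0 && any(std > cut, na.rm = TRUE)) ||
    any(fitted > 1 - 1e-10) || any(fitted < 1e-10)
}

fit_logistic <- function(X, y, penalty = 0.5, label = "model") {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  beta <- fit$coefficients
  aliased <- is.na(beta)
  beta[aliased] <- 0  # aliased (collinear) columns contribute nothing
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  penalized <- FALSE
  if (!fit$converged || detect_separation(X, beta, p)) {
    warning("(quasi-)separation in '", label,
            "'; falling back to ridge-penalized fit (penalty = ",
            penalty, ")")
    beta <- ridge_logistic(X, y, penalty)
    aliased <- rep(FALSE, length(beta))
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    penalized <- TRUE
  }
  loglik <- sum(dbinom(y, 1, p, log = TRUE))
  structure(list(coefficients = beta, fitted = p, loglik = loglik,
                 df = sum(!aliased), penalized = penalized, label = label,
                 y = y),
            class = "comanet_logit")
}

#' @export
print.comanet_logit <- function(x, ...) {
  cat("Logistic model '", x$label, "': ", x$df, " coefficients, logLik = ",
      round(x$loglik, 3), if (x$penalized) " (ridge-penalized)", "\n",
      sep = "")
  invisible(x)
}

# Ridge-penalized logistic regression by IRLS; the intercept (first
# column of X, all ones) is not penalized.
ridge_logistic <- function(X, y, lambda = 0.5, max_iter = 200,
                           tol = 1e-10) {
  p <- ncol(X)
  pen <- rep(lambda, p)
  if (all(X[, 1] == 1)) pen[1] <- 0
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    H <- crossprod(X * w, X) + diag(pen, p)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  names(beta) <- colnames(X)
  beta
}

#' ROC curve over all score thresholds
#'
#' Builds the full set of ROC operating points from a score vector, with
#' ties grouped (all subjects sharing a score cross a threshold
#' together), and the trapezoidal area under the curve.
#'
#' @param scores Numeric scores, higher = more indicative of the positive
#'   class.
#' @param labels Logical/0-1 vector: TRUE/1 for the positive class; both
#'   classes must be present.
#' @return Object of class `comanet_roc`: `points` (data.frame threshold,
#'   sensitivity, specificity) and `auc`.
#' @export
roc_analysis <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  if (length(scores) != length(y)) stop("scores and labels must align")
  if (anyNA(scores) || anyNA(y)) stop("missing scores or labels")
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1) / n_pos,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & y == 0) / n_neg,
                 numeric(1))
  pts <- data.frame(threshold = c(Inf, thr),
                    sensitivity = c(0, sens),
                    specificity = c(1, spec))
  fpr <- 1 - pts$specificity
  ord <- order(fpr, pts$sensitivity)
  auc <- sum(diff(fpr[ord]) *
             (pts$sensitivity[ord][-1] + pts$sensitivity[ord][-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc), class = "comanet_roc")
}

#' @export
print.comanet_roc <- function(x, ...) {
  cat("ROC with", nrow(x$points), "operating points, AUC =",
      round(x$auc, 4), "\n")
  invisible(x)
}

#' Maximum sensitivity at a specificity constraint
#'
#' The highest sensitivity among ROC operating points whose specificity
#' meets the constraint. The degenerate all-negative point (sensitivity 0,
#' specificity 1) always qualifies, so a model with no informative
#' qualifying threshold reports sensitivity 0.
#'
#' @param roc A `comanet_roc` from [roc_analysis()].
#' @param min_specificity Required specificity, in (0, 1].
#' @return Scalar sensitivity in \[0, 1\].
#' @export
sensitivity_at_specificity <- function(roc, min_specificity) {
  stopifnot(inherits(roc, "comanet_roc"))
  if (min_specificity <= 0 || min_specificity > 1)
    stop("min_specificity must lie in (0, 1]")
  ok <- roc$points$specificity >= min_specificity - 1e-12
  if (!any(ok)) return(0)
  max(roc$points$sensitivity[ok])
}

#' Likelihood-ratio test between nested logistic models
#'
#' 2 x (logLik_full - logLik_nested) referred to a chi-square with
#' degrees of freedom equal to the difference in coefficient counts.
#'
#' @param nested_fit,full_fit `comanet_logit` objects with the nested
#'   model's coefficients a subset of the full model's.
#' @return List: `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(nested_fit, full_fit) {
  df <- full_fit$df - nested_fit$df
  if (df < 0) stop("full model must have at least as many parameters")
  stat <- 2 * (full_fit$loglik - nested_fit$loglik)
  if (stat < -1e-6)
    stop("full-model log-likelihood below nested model's: fitting failure")
  stat <- max(stat, 0)
  if (df == 0) {
    # identical parameterizations: no test, trivially p = 1
    if (stat > 1e-6) stop("equal parameter counts but unequal likelihoods")
    return(list(statistic = 0, df = 0L, p = 1))
  }
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Evaluate a prognostic model at the guideline operating points
#'
#' For a fitted model predicting poor outcome, computes the apparent
#' (in-sample) ROC AUC, the sensitivity for good outcome at specificity at
#' least `spec_good` (good treated as positive; the score is re-poled), the
#' sensitivity for poor outcome at specificity >= `spec_poor`, and the
#' likelihood-ratio p value against an optional nested model.
#'
#' @param fit A `comanet_logit`.
#' @param nested_fit Optional nested `comanet_logit` for the LRT.
#' @param spec_good,spec_poor Specificity constraints for good-/poor-
#'   outcome sensitivity (defaults 0.90 and 1.00).
#' @return One-row data.frame: model_label, auc, sens_good, sens_poor,
#'   loglik, lrt_p.
#' @export
prediction_result <- function(fit, nested_fit = NULL,
                              spec_good = 0.90, spec_poor = 1.00) {
  stopifnot(inherits(fit, "comanet_logit"))
  y_poor <- fit$y
  roc_poor <- roc_analysis(fit$fitted, y_poor)
  roc_good <- roc_analysis(1 - fit$fitted, 1 - y_poor)
  # penalized (separation-fallback) likelihoods are not comparable by a
  # plain LRT; report NA rather than a misleading p value
  lrt_p <- if (is.null(nested_fit) || fit$penalized || nested_fit$penalized)
    NA_real_
  else likelihood_ratio_test(nested_fit, fit)$p
  data.frame(
    model_label = fit$label,
    auc = roc_poor$auc,
    sens_good = sensitivity_at_specificity(roc_good, spec_good),
    sens_poor = sensitivity_at_specificity(roc_poor, spec_poor),
    loglik = fit$loglik,
    lrt_p = lrt_p,
    stringsAsFactors = FALSE
  )
}

#' Compare the guideline model with graph-augmented models
#'
#' Fits the guideline model, each graph measure alone, and the guideline
#' model augmented with each measure; evaluates every model at the two
#' guideline operating points and tests each augmented model against the
#' guideline model by likelihood ratio.
#'
#' @param metadata Cohort metadata (see [fit_guideline_model()]).
#' @param metrics Data frame of graph-measure columns aligned with
#'   `metadata` rows.
#' @param metric_names Columns of `metrics` to use.
#' @inheritParams prediction_result
#' @inheritParams fit_guideline_model
#' @return Data frame with one row per model (guideline, each measure
#'   alone, guideline + each measure).
#' @export
compare_prediction_models <- function(metadata, metrics,
                                      metric_names = c(
                                        "whole_brain_fc", "clustering_auc",
                                        "global_efficiency_auc",
                                        "modularity_auc"),
                                      spec_good = 0.90, spec_poor = 1.00,
                                      penalty = 0.5) {
  guide <- fit_guideline_model(metadata, penalty = penalty)
  out <- list(prediction_result(guide, spec_good = spec_good,
                                spec_poor = spec_poor))
  for (m in metric_names) {
    alone <- augment_model(metadata, metrics[[m]], metric_name = m,
                           predictors = character(0), penalty = penalty)
    alone$label <- m
    out[[length(out) + 1]] <- prediction_result(alone, spec_good = spec_good,
                                                spec_poor = spec_poor)
    aug <- augment_model(metadata, metrics[[m]], metric_name = m,
                         penalty = penalty)
    out[[length(out) + 1]] <- prediction_result(aug, nested_fit = guide,
                                                spec_good = spec_good,
                                                spec_poor = spec_poor)
  }
  do.call(rbind, out)
}
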