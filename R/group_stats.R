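#' Between-group comparison with explicit test routing
#'
#' Continuous variables: Shapiro-Wilk normality is checked in each group
#' at alpha = 0.05 (groups smaller than 3 are treated as non-normal);
#' both normal routes to the classical pooled-variance t-test, otherwise
#' the Mann-Whitney U test is used. Categorical variables (a 2 x k
#' contingency table) use the chi-square test without continuity
#' correction, falling back to Fisher's exact test when any expected cell
#' count drops below 5.
#'
#' @param values_by_group For `kind = "continuous"` a list of two numeric
#'   vectors (n >= 2 each); for `"categorical"` a 2 x k contingency table.
#' @param kind `"continuous"` or `"categorical"`.
#' @param variable Optional variable name carried into the result.
#' @param test `"auto"` (the routing rule above) or an explicit
#'   `"t"`/`"mann_whitney"` override for continuous variables.
#' @return List of class `group_comparison`: `variable`, `test` (one of
#'   `"t"`, `"mann_whitney"`, `"chi_square"`, `"fisher_exact"`),
#'   `statistic`, `p`.
#' @export
compare_groups <- function(values_by_group,
                           kind = c("continuous", "categorical"),
                           variable = NA_character_,
                           test = c("auto", "t", "mann_whitney")) {
  kind <- match.arg(kind)
  test <- match.arg(test)
  if (kind == "continuous") {
    stopifnot(is.list(values_by_group), length(values_by_group) == 2)
    x <- values_by_group[[1]]
    y <- values_by_group[[2]]
    if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
    normal <- vapply(list(x, y), function(v) {
      if (length(v) < 3 || length(v) > 5000 || sd(v) == 0) return(FALSE)
      shapiro.test(v)$p.value > 0.05
    }, logical(1))
    use_t <- if (test == "auto") all(normal) else test == "t"
    if (use_t) {
      ht <- t.test(x, y, var.equal = TRUE)
      test <- "t"
    } else {
      ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
      test <- "mann_whitney"
    }
  } else {
    tab <- as.matrix(values_by_group)
    if (nrow(tab) != 2) stop("categorical comparison needs a 2 x k table")
    if (any(tab < 0)) stop("contingency counts must be non-negative")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ht <- fisher.test(tab)
      test <- "fisher_exact"
    } else {
      ht <- chisq.test(tab, correct = FALSE)
      test <- "chi_square"
    }
  }
  structure(list(variable = variable, test = test,
                 statistic = unname(if (is.null(ht$statistic)) NA_real_
                                    else ht$statistic),
                 p = unname(ht$p.value)),
            class = "group_comparison")
}

#' Cohen's d effect size
#'
#' Classical pooled-standard-deviation form: the difference of group means
#' divided by the pooled SD with n - 1 weighting.
#'
#' @param x,y Numeric vectors, n >= 2 each.
#' @return Scalar d (positive when `mean(x) > mean(y)`).
#' @export
cohens_d <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs n >= 2")
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 <= 0) stop("pooled variance is zero; Cohen's d undefined")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Covariate-adjusted group difference in a graph measure
#'
#' Logistic regression of the outcome on the graph measure while
#' controlling for the arrest-to-MRI interval, hospital (indicator
#' contrasts) and comatose state; returns the measure's coefficient and
#' its Wald two-sided p value. Poor outcome is the modelled event.
#'
#' @param metric Numeric vector, one value per subject.
#' @param outcome Character/factor of `"good"`/`"poor"` per subject.
#' @param covariates Data frame with columns `arrest_to_mri_h`, `hospital`
#'   and `comatose` (additional numeric/factor columns are allowed and
#'   entered additively).
#' @return List: `coefficient`, `se`, `p`, `fit` (the glm object).
#' @export
adjusted_group_difference <- function(metric, outcome, covariates) {
  y <- outcome_indicator(outcome, positive = "poor")
  df <- data.frame(.y = y, .metric = metric, covariates,
                   stringsAsFactors = TRUE)
  if (nrow(df) < ncol(df) + 2) stop("too few subjects for adjustment")
  mm <- model.matrix(.y ~ ., data = df)
  if (qr(mm)$rank < ncol(mm))
    stop("rank-deficient design: the measure is collinear with the ",
         "covariates")
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  if (!fit$converged) stop("logistic fit did not converge")
  sds <- apply(mm, 2, sd)
  std <- abs(coef(fit)[sds > 0]) * sds[sds > 0]
  if (any(std > 15, na.rm = TRUE) || any(fit$fitted.values > 1 - 1e-10) ||
      any(fit$fitted.values < 1e-10))
    stop("(quasi-)separation in the adjusted logistic model")
  est <- summary(fit)$coefficients[".metric", ]
  list(coefficient = unname(est["Estimate"]),
       se = unname(est["Std. Error"]),
       p = unname(est["Pr(>|z|)"]),
       fit = fit)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values (monotone, capped at 1, original order
#' preserved).
#'
#' @param p Numeric vector of p values in \[0, 1\] (NA passed through).
#' @return Adjusted p values.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Nodewise connectivity versus neurological outcome
#'
#' Pearson (point-biserial) correlation of each node's connectivity with
#' the binary outcome coded good = 1, poor = 0 (positive r means higher
#' connectivity with good outcome), with two-sided p values, plus the
#' counts of nodes significant at the three uncorrected levels 0.05, 0.01
#' and 0.001. Nodes with constant connectivity across subjects are
#' recorded as missing and excluded from the counts.
#'
#' @param nodewise Subjects x nodes matrix of nodewise connectivity.
#' @param outcomes Character/factor of `"good"`/`"poor"`, both present.
#' @return List: `results` (data.frame node_index, r, p) and `counts`
#'   (named vector p05/p01/p001).
#' @export
nodewise_outcome_correlation <- function(nodewise, outcomes) {
  y <- outcome_indicator(outcomes, positive = "good")
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  if (nrow(nodewise) != length(y))
    stop("nodewise rows must match the number of outcomes")
  res <- lapply(seq_len(ncol(nodewise)), function(j) {
    v <- nodewise[, j]
    if (sd(v) == 0)
      return(data.frame(node_index = j, r = NA_real_, p = NA_real_))
    ct <- cor.test(v, y)
    data.frame(node_index = j, r = unname(ct$estimate),
               p = ct$p.value)
  })
  res <- do.call(rbind, res)
  counts <- c(p05 = sum(res$p < 0.05, na.rm = TRUE),
              p01 = sum(res$p < 0.01, na.rm = TRUE),
              p001 = sum(res$p < 0.001, na.rm = TRUE))
  list(results = res, counts = counts)
}

#' Graph measures across EEG categories
#'
#' Kruskal-Wallis omnibus test of a whole-brain measure over the EEG
#' background categories; when the omnibus test is significant at `alpha`,
#' all pairwise Mann-Whitney U contrasts are run and FDR-adjusted,
#' otherwise the pairwise stage is suppressed. Categories with fewer than
#' 2 subjects are excluded with a warning.
#'
#' @param values Numeric vector of the measure, one value per subject.
#' @param categories Vector of EEG category labels per subject.
#' @param alpha Gate for the pairwise stage (default 0.05).
#' @return List: `omnibus` (statistic, df, p, categories used) and
#'   `pairwise` (data.frame cat1, cat2, statistic, p_raw, p_fdr; NULL when
#'   suppressed).
#' @export
eeg_category_tests <- function(values, categories, alpha = 0.05) {
  categories <- as.character(categories)
  tab <- table(categories)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warning("excluding EEG categories with n < 2: ",
            paste(small, collapse = ", "))
    keep <- !(categories %in% small)
    values <- values[keep]
    categories <- categories[keep]
  }
  cats <- sort(unique(categories))
  if (length(cats) < 2) stop("need at least 2 categories with n >= 2")
  kw <- kruskal.test(values, factor(categories))
  pairwise <- NULL
  if (kw$p.value < alpha) {
    pairs <- utils::combn(cats, 2)
    pw <- apply(pairs, 2, function(pr) {
      ht <- suppressWarnings(
        wilcox.test(values[categories == pr[1]],
                    values[categories == pr[2]], exact = FALSE))
      c(statistic = unname(ht$statistic), p = ht$p.value)
    })
    pairwise <- data.frame(cat1 = pairs[1, ], cat2 = pairs[2, ],
                           statistic = pw["statistic", ],
                           p_raw = pw["p", ],
                           p_fdr = fdr_adjust(pw["p", ]),
                           stringsAsFactors = FALSE)
  }
  list(omnibus = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter),
                      p = kw$p.value,
                      categories = cats),
       pairwise = pairwise)
}

#' Pairwise correlations among whole-brain graph measures
#'
#' Pearson correlations (with two-sided p values) between every pair of
#' measure columns across subjects; constant columns yield missing
#' entries.
#'
#' @param metric_table Data frame or matrix of numeric measure columns
#'   (>= 3 subjects).
#' @return List of symmetric matrices `r` and `p`.
#' @export
metric_correlations <- function(metric_table) {
  m <- as.matrix(metric_table)
  if (nrow(m) < 3) stop("need at least 3 subjects")
  k <- ncol(m)
  r <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  p <- r
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (sd(m[, i]) == 0 || sd(m[, j]) == 0) next
      ct <- cor.test(m[, i], m[, j])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p)
}

# 0/1 indicator of the requested outcome class
outcome_indicator <- function(outcome, positive = c("poor", "good")) {
  positive <- match.arg(positive)
  o <- as.character(outcome)
  bad <- setdiff(unique(o), c("good", "poor"))
  if (length(bad) > 0)
    stop("outcome labels must be 'good'/'poor'; found: ",
         paste(bad, collapse = ", "))
  as.integer(o == positive)
}
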