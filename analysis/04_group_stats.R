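#!/usr/bin/env Rscript
# Stage 4: group statistics. Between-group comparisons of the four
# whole-brain measures (routed t / Mann-Whitney, Cohen's d,
# covariate-adjusted logistic contrasts, FDR across the four measures),
# correlations among the measures, nodewise outcome correlations at the
# three uncorrected significance levels, and EEG-category contrasts.

suppressPackageStartupMessages(library(comanet))

md <- read_cohort_metadata("scratch/cohort/metadata.csv")
metrics <- read.csv("results/metrics.csv")
nodewise_df <- read.csv("scratch/nodewise.csv")
nodewise <- as.matrix(nodewise_df[, -1])
stopifnot(identical(md$subject_id, metrics$subject_id))

measures <- c("whole_brain_fc", "clustering_auc",
              "global_efficiency_auc", "modularity_auc")
good <- md$outcome == "good"
covars <- md[, c("arrest_to_mri_h", "hospital", "comatose")]

comparisons <- do.call(rbind, lapply(measures, function(m) {
  x <- metrics[[m]][good]
  y <- metrics[[m]][!good]
  cmp <- compare_groups(list(good = x, poor = y), "continuous",
                        variable = m)
  adj <- tryCatch(
    adjusted_group_difference(metrics[[m]], md$outcome, covars)$p,
    error = function(e) {
      cat(sprintf("  [%s] adjusted model: %s\n", m, conditionMessage(e)))
      NA_real_
    })
  data.frame(variable = m, test = cmp$test, statistic = cmp$statistic,
             p_raw = cmp$p, cohen_d = cohens_d(x, y), adjusted_p = adj,
             median_good = median(x), median_poor = median(y))
}))
comparisons$p_fdr <- fdr_adjust(comparisons$p_raw)
write.csv(comparisons, "results/comparisons.csv", row.names = FALSE)
cat("Group comparisons (good vs poor):\n")
print(comparisons[, c("variable", "test", "p_raw", "p_fdr", "cohen_d",
                      "median_good", "median_poor")], row.names = FALSE)

mc <- metric_correlations(metrics[, measures])
write.csv(round(mc$r, 4), "results/metric_correlations.csv")
cat(sprintf("\nr(FC, clustering) = %.2f (p = %.2g)\n",
            mc$r["whole_brain_fc", "clustering_auc"],
            mc$p["whole_brain_fc", "clustering_auc"]))

nw <- nodewise_outcome_correlation(nodewise, md$outcome)
write.csv(nw$results, "results/nodewise.csv", row.names = FALSE)
cat(sprintf("\nNodes correlated with outcome: %d at p<0.05, %d at p<0.01, %d at p<0.001 (of %d)\n",
            nw$counts[["p05"]], nw$counts[["p01"]], nw$counts[["p001"]],
            ncol(nodewise)))

eeg_rows <- list()
for (m in measures) {
  et <- suppressWarnings(
    tryCatch(eeg_category_tests(metrics[[m]], md$eeg_category_label),
             error = function(e) NULL))
  if (is.null(et)) next
  eeg_rows[[m]] <- data.frame(variable = m,
                              statistic = et$omnibus$statistic,
                              df = et$omnibus$df, p = et$omnibus$p)
  cat(sprintf("\nKruskal-Wallis %s over EEG categories: H = %.2f, p = %.3g\n",
              m, et$omnibus$statistic, et$omnibus$p))
  if (!is.null(et$pairwise)) {
    sig <- et$pairwise[et$pairwise$p_fdr < 0.05, ]
    if (nrow(sig) > 0) {
      cat("  significant pairwise contrasts (FDR < 0.05):\n")
      print(sig, row.names = FALSE)
    }
    write.csv(et$pairwise,
              sprintf("results/eeg_pairwise_%s.csv", m),
              row.names = FALSE)
  }
}
write.csv(do.call(rbind, eeg_rows), "results/eeg_omnibus.csv",
          row.names = FALSE)
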