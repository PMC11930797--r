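#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes every stage end to end on a simulated cohort: cohort
#' generation, per-subject connectivity, density-thresholded graph
#' measures with AUC surrogates, between-group statistics with Cohen's d,
#' covariate adjustment and FDR control, nodewise outcome correlations,
#' EEG-category contrasts, and guideline-vs-augmented prognostic model
#' comparison. Deterministic given the config seed. When `out_dir` is
#' given, every stage's tables plus the resolved config are written there
#' as CSV/YAML.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional output directory.
#' @param densities Density grid (default [density_grid()]).
#' @param discard_first_k Leading volumes dropped per subject (default 5).
#' @param gamma,n_restarts Louvain settings (defaults 1 and 100).
#' @param alpha Significance level gating pairwise EEG contrasts.
#' @param spec_good,spec_poor Specificity constraints of the prediction
#'   stage.
#' @param write_matrices Also write each subject's connectivity matrix?
#'   Default FALSE (they are large).
#' @return List of class `comanet_results`: `metadata`, `metrics`,
#'   `nodewise` (matrix), `comparisons`, `nodewise_stats`,
#'   `metric_correlations`, `eeg_tests`, `prediction`, `config`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         densities = density_grid(), discard_first_k = 5,
                         gamma = 1, n_restarts = 100, alpha = 0.05,
                         spec_good = 0.90, spec_poor = 1.00,
                         write_matrices = FALSE) {
  cohort <- generate_cohort(config)
  md <- cohort$metadata

  gm <- cohort_graph_metrics(cohort, densities = densities,
                             discard_first_k = discard_first_k,
                             gamma = gamma, n_restarts = n_restarts,
                             seed = config$seed)
  metrics <- gm$metrics

  measure_cols <- c("whole_brain_fc", "clustering_auc",
                    "global_efficiency_auc", "modularity_auc")
  good <- md$outcome == "good"
  covars <- md[, c("arrest_to_mri_h", "hospital", "comatose")]

  comparisons <- do.call(rbind, lapply(measure_cols, function(m) {
    x <- metrics[[m]][good]
    y <- metrics[[m]][!good]
    cmp <- compare_groups(list(good = x, poor = y), "continuous",
                          variable = m)
    adj <- tryCatch(
      adjusted_group_difference(metrics[[m]], md$outcome, covars)$p,
      error = function(e) NA_real_)
    data.frame(variable = m, test = cmp$test, statistic = cmp$statistic,
               p_raw = cmp$p, cohen_d = cohens_d(x, y), adjusted_p = adj,
               median_good = median(x), median_poor = median(y),
               stringsAsFactors = FALSE)
  }))
  comparisons$p_fdr <- fdr_adjust(comparisons$p_raw)

  nodewise_stats <- nodewise_outcome_correlation(gm$nodewise, md$outcome)
  mcor <- metric_correlations(metrics[, measure_cols])

  eeg_tests <- lapply(setNames(measure_cols, measure_cols), function(m)
    tryCatch(eeg_category_tests(metrics[[m]], md$eeg_category_label,
                                alpha = alpha),
             error = function(e) NULL))

  prediction <- compare_prediction_models(md, metrics,
                                          metric_names = measure_cols,
                                          spec_good = spec_good,
                                          spec_poor = spec_poor)

  res <- structure(list(metadata = md, metrics = metrics,
                        nodewise = gm$nodewise,
                        comparisons = comparisons,
                        nodewise_stats = nodewise_stats,
                        metric_correlations = mcor,
                        eeg_tests = eeg_tests,
                        prediction = prediction,
                        config = config),
                   class = "comanet_results")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(md, file.path(out_dir, "metadata.csv"), row.names = FALSE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
              row.names = FALSE)
    write.csv(nodewise_stats$results, file.path(out_dir, "nodewise.csv"),
              row.names = FALSE)
    write.csv(prediction, file.path(out_dir, "prediction.csv"),
              row.names = FALSE)
    eeg_rows <- do.call(rbind, lapply(names(eeg_tests), function(m) {
      et <- eeg_tests[[m]]
      if (is.null(et)) return(NULL)
      data.frame(variable = m, statistic = et$omnibus$statistic,
                 df = et$omnibus$df, p = et$omnibus$p,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(eeg_rows))
      write.csv(eeg_rows, file.path(out_dir, "eeg_omnibus.csv"),
                row.names = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    if (write_matrices) {
      mat_dir <- file.path(out_dir, "connectivity")
      dir.create(mat_dir, showWarnings = FALSE)
      for (s in cohort$subjects)
        write_connectivity(subject_connectivity(s$timeseries,
                                                discard_first_k),
                           file.path(mat_dir,
                                     paste0(s$subject_id, "_conn.tsv")))
    }
  }
  res
}

#' @export
print.comanet_results <- function(x, ...) {
  cat("comanet pipeline results:", nrow(x$metadata), "subjects\n\n")
  cat("Group comparisons (good vs poor):\n")
  print(x$comparisons[, c("variable", "test", "p_raw", "p_fdr", "cohen_d",
                          "adjusted_p")], row.names = FALSE)
  cat("\nNodewise counts:",
      paste(names(x$nodewise_stats$counts), x$nodewise_stats$counts,
            sep = " = ", collapse = ", "), "\n")
  cat("\nPrediction models:\n")
  print(x$prediction[, c("model_label", "auc", "sens_good", "sens_poor",
                         "lrt_p")], row.names = FALSE)
  invisible(x)
}
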