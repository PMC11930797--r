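# comanet

Functional-connectome graph analysis for neurological outcome prognosis
in comatose patients after cardiac arrest.

Early resting-state fMRI offers a whole-brain view of hypoxic-ischemic
encephalopathy. `comanet` implements the full analysis from parcellated
node time series to prognostic model comparison, for researchers
evaluating whether graph measures of network integration and segregation
add predictive value to established guideline criteria — and, because no
patient data accompany the method, ships a seeded synthetic-cohort
generator so every stage is testable and reproducible end to end.

## The analysis

For each subject with an N x T node time-series table (default 264
nodes, 220 volumes):

- **Connectivity** — pairwise Pearson correlations of z-scored series,
  Fisher Z-transformed (`z = artanh r`), negative edges zeroed. Whole-brain
  functional connectivity (FC) is the mean positive edge weight; nodewise
  connectivity is each node's mean edge weight to the other N − 1 nodes.
- **Graph measures over a density grid** — proportional thresholding
  retains the top `round(d·N(N−1)/2)` edges for d = 5%…45% in steps of
  5% (nine thresholds). On each weighted thresholded graph: Onnela
  clustering coefficient C, global efficiency GE (mean inverse
  shortest-path length with lengths 1/w), and Louvain modularity Q
  (Newman–Girvan weighted, 100 seeded restarts). Each measure is
  summarised by its area under the curve over the nine densities
  (trapezoid, normalized by the density span).
- **Group statistics** — t / Mann-Whitney routing by Shapiro-Wilk,
  Cohen's d, covariate-adjusted logistic contrasts (arrest-to-MRI time,
  hospital, comatose state), Benjamini-Hochberg FDR; nodewise
  point-biserial correlations with outcome at three uncorrected levels;
  Kruskal-Wallis plus FDR-adjusted pairwise contrasts across EEG
  background categories.
- **Prognostic models** — logistic regression of poor outcome on the
  guideline predictors (combined fixed-pupils/absent-SSEP indicator and
  guideline EEG class), with and without each graph measure; compared by
  ROC AUC, sensitivity for good outcome at specificity ≥ 90%, sensitivity
  for poor outcome at specificity = 100%, and likelihood-ratio tests.

## Worked example

```r
library(comanet)

cfg <- cohort_config(n_good = 30, n_poor = 18, n_nodes = 24,
                     n_volumes = 120, n_modules = 4, seed = 11)
res <- run_pipeline(cfg, n_restarts = 25)
print(res)
```

```
comanet pipeline results: 48 subjects

Group comparisons (good vs poor):
              variable         test        p_raw        p_fdr  cohen_d adjusted_p
        whole_brain_fc            t 5.595410e-08 2.238164e-07 1.930576         NA
        clustering_auc mann_whitney 5.446983e-05 5.446983e-05 1.760396         NA
 global_efficiency_auc mann_whitney 2.947469e-06 5.894939e-06 2.026778         NA
        modularity_auc mann_whitney 2.600022e-05 3.466696e-05 1.682575         NA

Nodewise counts: p05 = 24, p01 = 24, p001 = 24

Prediction models:
                     model_label       auc sens_good sens_poor        lrt_p
                       guideline 0.7962963 0.0000000 0.4444444           NA
                  whole_brain_fc 0.9000000 0.5666667 0.3888889           NA
        guideline+whole_brain_fc 0.9296296 0.6666667 0.7222222 1.232838e-04
                  clustering_auc 0.8518519 0.5000000 0.5000000           NA
        guideline+clustering_auc 0.9018519 0.4333333 0.7222222 2.445439e-04
           global_efficiency_auc 0.9074074 0.7333333 0.3888889           NA
 guideline+global_efficiency_auc 0.9407407 0.7333333 0.7777778 3.493757e-05
                  modularity_auc 0.8666667 0.5000000 0.5000000           NA
        guideline+modularity_auc 0.9129630 0.4666667 0.7222222 2.537881e-04
```

Reading the output: whole-brain FC and all three AUC surrogates are
lower in the poor-outcome group (large Cohen's d, FDR-significant). The
guideline model alone cannot identify any good-outcome patient at ≥ 90%
specificity (`sens_good = 0`); adding any graph measure raises that
sensitivity to 0.43–0.73 and improves the fit (likelihood-ratio p <
0.001). `adjusted_p` is NA here because the covariate-adjusted model
quasi-separates in this small synthetic cohort (the comatose covariate
is nearly deterministic for poor outcome, as in the real baseline
table); the pipeline reports the diagnostic rather than a meaningless
Wald p.

The numbered scripts under `analysis/` run the same stages file-by-file
at the full default scale (70 subjects, 264 nodes): simulate →
connectivity → graph measures → group statistics → prediction, writing
summary tables under `results/` and subject-level intermediates under
`scratch/`.

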