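---
title: "Methods: functional connectome graph analysis for coma outcome prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional connectome graph analysis for coma outcome prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(comanet)
```

## The problem

Comatose survivors of cardiac arrest carry diffuse hypoxic-ischemic brain
injury, and early, accurate prognosis drives treatment decisions up to
and including withdrawal of life-sustaining therapy. Established
guideline predictors (bilaterally absent pupillary reflexes and/or
somatosensory evoked potentials, and the early EEG background pattern)
are specific for poor outcome but leave many patients indeterminate.
`comanet` implements a whole-brain analysis of early resting-state fMRI:
it quantifies functional integration and segregation of the parcellated
brain network by graph measures, relates them to six-month neurological
outcome (good: no/mild impairment vs poor: severe impairment, vegetative
state or death) and to EEG background categories, and asks whether graph
measures add prognostic value to a guideline-based logistic model.

The pipeline starts at parcellated node time series (nodes x volumes
tables); MRI preprocessing, grey-matter masking and voxel-to-node
extraction are upstream and out of scope, as are EEG recording and
classification (the EEG category arrives as a label).

## Pipeline

For each subject with an $N \times T$ time-series matrix (default
$N = 264$ nodes, $T = 220$ volumes, first 5 discarded for steady state):

1. **Connectivity.** Node series are z-scored and all pairwise Pearson
   correlations computed. The matrix is normalized by the Fisher
   Z-transformation $z = \operatorname{artanh}(r)$; negative
   correlations are set to zero; the diagonal is zero. Whole-brain
   functional connectivity (FC) is the mean of the strictly positive
   edges (each unordered pair counted once); nodewise connectivity is
   each node's row mean over the $N-1$ other nodes, zeroed edges
   included.
2. **Proportional density thresholding.** For each density $d$ in the
   grid 5% to 45% in steps of 5% (nine thresholds), the
   $\mathrm{round}(d\,N(N-1)/2)$ strongest edges are retained with their
   weights, so all subjects are compared at equal edge counts. Ties at
   the cutoff break deterministically by (weight descending, edge index
   ascending).
3. **Graph measures.** On each thresholded weighted graph:
   the mean Onnela clustering coefficient
   $C_i = \frac{2}{k_i(k_i-1)}\sum_{jh}(\tilde w_{ij}\tilde w_{ih}\tilde w_{jh})^{1/3}$
   with weights rescaled by the global maximum (nodes with degree < 2
   contribute 0); global efficiency, the mean over ordered pairs of
   $1/d(i,j)$ with connection lengths $1/w$ and Dijkstra shortest paths
   (disconnected pairs contribute 0); and modularity, the best
   Newman–Girvan weighted $Q$ at resolution $\gamma = 1$ found by 100
   seeded Louvain restarts. Each measure's curve over the nine densities
   is collapsed to an area-under-curve surrogate by the trapezoidal rule
   normalized by the density span, so the surrogate lives on the
   measure's own scale and a constant curve returns its constant.
4. **Group statistics.** Good vs poor outcome is compared per measure by
   a t-test when both groups pass Shapiro-Wilk normality at
   $\alpha = 0.05$, otherwise Mann-Whitney U; effect sizes are classical
   pooled-SD Cohen's d; covariate-adjusted contrasts come from logistic
   regression of outcome on the measure plus arrest-to-MRI interval,
   hospital, and comatose state; the four raw p values are
   Benjamini-Hochberg adjusted. Nodewise connectivity is correlated with
   outcome (point-biserial, good coded 1) and reported uncorrected at
   p < 0.05/0.01/0.001, as is conventional for nodewise maps.
   Measures are compared across EEG categories by Kruskal-Wallis with
   FDR-adjusted pairwise Mann-Whitney contrasts gated on the omnibus
   test.
5. **Prognostic models.** The guideline model is a maximum-likelihood
   logistic regression of poor outcome on the combined pupils/SSEP
   indicator and the guideline EEG class (good / poor / indifferent,
   treatment contrasts against indifferent). Augmented models append one
   graph measure, preserving nesting for the likelihood-ratio test.
   Models are evaluated in-sample by the ROC area and by the maximum
   sensitivity among operating points meeting the guideline specificity
   constraints: at least 90% specificity with good outcome as the
   positive class (score re-poled), and 100% specificity with poor
   outcome positive. The degenerate all-negative operating point
   (sensitivity 0 at specificity 1) always qualifies, so an uninformative
   model reports sensitivity 0 rather than failing.

## The synthetic cohort generator

No patient data are distributed, so a seeded generator stands in for the
cohort; it is first-class, tested code, and the whole cohort is a pure
function of its configuration. Each subject's signal is a zero-mean
multivariate normal with a modular block covariance: unit variances,
correlation `coupling * rho_within` inside `n_modules` equal blocks and
`coupling * rho_between` between blocks, plus i.i.d. Gaussian
observation noise. Defaults (chosen once):

| parameter | default | rationale |
|---|---|---|
| `n_good`, `n_poor` | 44, 26 | reference cohort size |
| `n_nodes`, `n_volumes` | 264, 220 | parcellation and acquisition length |
| `n_modules` | 8 | a coarse community structure of the cortical parcellation |
| `rho_within`, `rho_between` | 0.7, 0.3 | with `noise_sd = 0.4` and couplings 0.9/0.6, the analytic mean positive Fisher-z edge lands near 0.28 (good) and 0.18 (poor), the published whole-brain FC scale |
| `coupling_good`, `coupling_poor` | 0.9, 0.6 | group contrast in global coupling |
| `coupling_sd_logit` | 1.2 | per-subject coupling jitter on the logit scale; see below |
| `noise_sd` | 0.4 | attenuates observed correlations by a factor 1/(1+0.16) |

Observed correlations attenuate as
$\rho_{\text{obs}} = \rho_{\text{sig}}/(1+\sigma^2_{\text{noise}})$, which
is how the FC scale above is derived.

**Between-subject heterogeneity.** With a fixed group coupling the only
between-subject FC variance is finite-$T$ sampling noise, which at 264
nodes averages away over ~35k edges; groups then separate almost
perfectly (effect sizes > 5), which no clinical cohort shows and which
makes every logistic model quasi-separate. Each subject's coupling is
therefore drawn on the logit scale around the group value with SD 1.2,
calibrated at near-default scale (48 nodes, 220 volumes) to give
between-group Cohen's d of order 1-2 — the scale of the published
effects (FC d = 1.09, clustering d = 0.82) — and overlapping group
distributions.

**Labels and covariates.** EEG categories (suppressed; suppressed with
pathological bursts/GPDs; continuous; epileptiform; burst suppression)
are drawn from outcome-conditional multinomials whose defaults enrich
continuous activity in good outcome and reproduce the published
category sizes (~9/30/7/14 over the four non-suppressed classes at
44/26). The guideline EEG class and the pupils/SSEP indicator are
likewise outcome-linked multinomials/Bernoullis; their strengths are
free parameters, not estimates — the source study gives no quantitative
link between EEG category and connectivity beyond group medians.
Covariates follow the published baseline table: arrest-to-MRI interval
Normal(59, 21) h (good) vs Normal(66, 27) h (poor), three hospitals
uniformly, comatose-during-MRI Bernoulli(0.36/0.96).

**What the generator does not emulate:** BOLD hemodynamics, scanner
drift, head motion, physiological noise, regional (node-specific)
vulnerability, or negative correlations' spatial structure. Because the
group contrast is a *global* coupling shift, essentially every node
correlates with outcome in large synthetic cohorts — unlike real data,
where roughly half the nodes did, with a posterior gradient. Passing
tests therefore validate the pipeline's computations and calibration,
not the spatial specificity of real connectomes.

## Numerical and design choices

- **"Average of all positive edges"** is read literally: the
  denominator counts strictly positive edges only. The alternative
  (zeroed negatives in the denominator) is available via
  `include_zeros = TRUE` in `whole_brain_fc()`.
- **Nodewise connectivity** is computed on the normalized (Fisher-z,
  negatives-zeroed) matrix with an $N-1$ denominator, keeping a single
  matrix representation throughout.
- **Graphs stay weighted after thresholding**; a `binarize` switch
  reduces every measure to its binary variant.
- **Onnela rescaling** by the global maximum weight keeps the clustering
  coefficient in [0, 1]; the oracle tests use the same convention.
- **Louvain** restarts use random *improving* moves rather than
  best-gain moves (best-gain funnels every restart into the same basin),
  followed by a deterministic single-node refinement and community-level
  re-optimization until $Q$ stabilizes. On 1000 random graphs of up to 8
  nodes, 100 restarts recovered the exhaustive-search optimum every
  time. Identical seed implies identical result.
- **Separation handling.** Logistic fits are declared (quasi-)separated
  when any coefficient exceeds 15 logits per predictor SD or any fitted
  probability is numerically 0/1; scale-free thresholds on raw
  coefficients misfire badly for small-scale predictors such as FC
  (a coefficient of -54 per FC unit is an ordinary effect). Prognostic
  models fall back to a ridge-penalized IRLS fit (penalty 0.5 on
  non-intercept coefficients) with a warning; the reported
  log-likelihood is always the unpenalized likelihood at the returned
  coefficients, and likelihood-ratio p values are withheld (NA) when
  either model is penalized. The covariate-adjusted group contrast
  instead raises a diagnostic error, since a separated Wald p is
  meaningless. With the comatose rate at its default 0.96 in poor
  outcome, quasi-separation at n = 70 is *expected* behavior — the
  reference cohort itself had 25/26 poor-outcome patients comatose.
- **Aliased columns** (e.g. a constant added metric) are dropped from
  the coefficient count, so augmenting with an uninformative constant
  leaves the log-likelihood and the LRT degrees of freedom unchanged.
- **Ties in predicted probability** cross ROC thresholds together
  (group thresholding), making operating points deterministic.

## Simulation studies in the test suite

The suite's calibration and recovery studies use reduced problem sizes,
chosen as the package's own simulation design:

- *Type-I calibration*: 1000 null cohorts (equal couplings) of 30 + 30
  subjects, 16 nodes, 60 volumes. Mann-Whitney, the covariate-adjusted
  Wald contrast, nodewise correlation, Kruskal-Wallis over EEG
  categories, and the likelihood-ratio test must all reject within
  0.02-0.08 at nominal 0.05 (Monte-Carlo error plus finite-sample slack
  of the Wald/chi-square references).
- *Effect recovery*: 100 cohorts of 44 + 26 subjects, 30 nodes, 120
  volumes, couplings 0.9 vs 0.5: the good group's median FC is higher
  and r(FC, clustering AUC) > 0.7 in at least 95 of 100 replicates, and
  an informative measure raises the guideline model's log-likelihood in
  every non-degenerate replicate.
- In these reduced-n studies the comatose and guideline-predictor rates
  are softened (e.g. comatose 0.35/0.75) so that the *covariates* do not
  quasi-separate the models — at n = 60, a 0.96 comatose rate leaves all
  poor-outcome subjects comatose in ~30% of draws, which tests the
  separation diagnostic rather than the statistic under study. The
  diagnostic paths have their own tests.
- *Oracle equivalence*: on 200 random graphs of 4-8 nodes, clustering is
  checked against exhaustive triangle enumeration, global efficiency
  against Floyd-Warshall, modularity against exhaustive set-partition
  search, and thresholding against the sorted edge count.

## Known limitations

- In-sample (apparent) AUC and sensitivities only, matching the source
  analysis; no cross-validation or optimism correction is applied.
- The Wald p of the adjusted contrast degrades near separation
  (Hauck-Donner); the pipeline reports the diagnostic instead of a
  number there.
- The modularity AUC inherits Louvain's stochasticity; it is
  reproducible only through the seed.
- The generator's global-coupling contrast makes nodewise maps spatially
  uniform; regional effects cannot be studied synthetically without
  extending the covariance model.
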