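#' EEG background categories at 24 h
#'
#' Five-level visual classification of the EEG background pattern at 24 h
#' after cardiac arrest, used throughout the package: 1 suppressed,
#' 2 suppressed with pathological bursts or generalized periodic
#' discharges (GPDs), 3 continuous activity, 4 epileptiform activity,
#' 5 discontinuous or heterogeneous burst suppression.
#'
#' @format Character vector of length 5, indexed by category number.
#' @export
eeg_category_labels <- c(
  "suppressed",
  "suppressed_bursts_gpd",
  "continuous",
  "epileptiform",
  "burst_suppression"
)

default_eeg_probs <- function() {
  p <- rbind(
    good = c(0.05, 0.05, 0.60, 0.10, 0.20),
    poor = c(0.30, 0.25, 0.10, 0.15, 0.20)
  )
  colnames(p) <- eeg_category_labels
  p
}

default_guideline_eeg_probs <- function() {
  p <- rbind(
    good = c(good = 0.50, indifferent = 0.48, poor = 0.02),
    poor = c(good = 0.05, indifferent = 0.55, poor = 0.40)
  )
  p
}

#' Configuration of a synthetic two-group cohort
#'
#' Defines the study conditions of a simulated cardiac-arrest cohort: a
#' modular block-covariance signal process whose global off-diagonal
#' coupling differs between the good- and poor-outcome groups, plus
#' outcome-linked EEG categories, guideline predictors and clinical
#' covariates. Defaults emulate the reference cohort: 44 good / 26 poor
#' outcome subjects, 264 nodes, 220 volumes, and covariate distributions
#' matching the published baseline table (arrest-to-MRI interval
#' Normal(59, 21) h good vs Normal(66, 27) h poor; comatose-during-MRI
#' rate 0.36 vs 0.96; three hospitals).
#'
#' @param n_good,n_poor Number of good- and poor-outcome subjects.
#' @param n_nodes Number of nodes (parcels).
#' @param n_volumes Time points per subject.
#' @param n_modules Number of equally sized covariance blocks.
#' @param rho_within Within-module correlation, in \[0, 1).
#' @param rho_between Between-module correlation, in \[0, rho_within\].
#' @param coupling_good,coupling_poor Global multipliers in (0, 1\] applied
#'   to all off-diagonal covariance, one per outcome group.
#' @param coupling_sd_logit Between-subject heterogeneity: each subject's
#'   coupling is drawn around the group value on the logit scale with this
#'   standard deviation (0 disables jitter). Gives overlapping group
#'   distributions with effect sizes of order 1 instead of the degenerate
#'   near-separation a fixed group coupling would produce.
#' @param noise_sd Standard deviation of additive i.i.d. Gaussian
#'   observation noise (signal variance is 1).
#' @param eeg_probs 2 x 5 matrix of outcome-conditional EEG-category
#'   probabilities (rows `good`, `poor`; rows sum to 1). The defaults
#'   enrich continuous activity in good outcome.
#' @param guideline_eeg_probs 2 x 3 matrix of outcome-conditional
#'   probabilities for the guideline EEG class (good/indifferent/poor).
#' @param pupils_ssep_prob Named vector: probability of bilaterally absent
#'   pupillary reflexes and/or absent SSEPs, by outcome group.
#' @param arrest_to_mri List with `good` and `poor` elements, each
#'   c(mean, sd) in hours for the arrest-to-MRI interval.
#' @param n_hospitals Number of study sites (uniformly assigned).
#' @param comatose_prob Named vector: probability of being comatose during
#'   the MRI, by outcome group.
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return A `cohort_config` object (validated list).
#' @export
cohort_config <- function(n_good = 44, n_poor = 26,
                          n_nodes = 264, n_volumes = 220,
                          n_modules = 8,
                          rho_within = 0.7, rho_between = 0.3,
                          coupling_good = 0.9, coupling_poor = 0.6,
                          coupling_sd_logit = 1.2,
                          noise_sd = 0.4,
                          eeg_probs = default_eeg_probs(),
                          guideline_eeg_probs = default_guideline_eeg_probs(),
                          pupils_ssep_prob = c(good = 0.02, poor = 0.45),
                          arrest_to_mri = list(good = c(59, 21),
                                               poor = c(66, 27)),
                          n_hospitals = 3,
                          comatose_prob = c(good = 0.36, poor = 0.96),
                          seed = 1L) {
  cfg <- list(
    n_good = as.integer(n_good), n_poor = as.integer(n_poor),
    n_nodes = as.integer(n_nodes), n_volumes = as.integer(n_volumes),
    n_modules = as.integer(n_modules),
    rho_within = rho_within, rho_between = rho_between,
    coupling_good = coupling_good, coupling_poor = coupling_poor,
    coupling_sd_logit = coupling_sd_logit,
    noise_sd = noise_sd,
    eeg_probs = eeg_probs,
    guideline_eeg_probs = guideline_eeg_probs,
    pupils_ssep_prob = pupils_ssep_prob,
    arrest_to_mri = arrest_to_mri,
    n_hospitals = as.integer(n_hospitals),
    comatose_prob = comatose_prob,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_good > 0, cfg$n_poor > 0,
    cfg$n_nodes >= 2, cfg$n_volumes >= 3,
    cfg$n_modules >= 1, cfg$n_modules <= cfg$n_nodes,
    cfg$noise_sd >= 0, cfg$n_hospitals >= 1, cfg$coupling_sd_logit >= 0
  )
  if (cfg$rho_within < 0 || cfg$rho_within >= 1)
    stop("rho_within must lie in [0, 1)")
  if (cfg$rho_between < 0 || cfg$rho_between > cfg$rho_within)
    stop("rho_between must lie in [0, rho_within]")
  for (cp in c(cfg$coupling_good, cfg$coupling_poor))
    if (cp <= 0 || cp > 1) stop("couplings must lie in (0, 1]")
  for (p in list(cfg$eeg_probs, cfg$guideline_eeg_probs)) {
    if (!all(rownames(p) == c("good", "poor")))
      stop("probability matrices need rows 'good' and 'poor'")
    if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-8))
      stop("probability rows must be non-negative and sum to 1")
  }
  invisible(cfg)
}

#' Modular block covariance matrix
#'
#' Builds the population covariance of the synthetic signal process:
#' unit diagonal, `coupling * rho_within` inside equally sized modules and
#' `coupling * rho_between` between modules. The construction is positive
#' semi-definite whenever `0 <= rho_between <= rho_within < 1` and
#' `coupling` is in (0, 1]; the minimum eigenvalue is checked regardless
#' and invalid parameterizations are rejected.
#'
#' @param n_nodes Number of nodes.
#' @param n_modules Number of blocks; nodes are split as evenly as possible.
#' @param rho_within,rho_between Within-/between-module correlations.
#' @param coupling Global multiplier in (0, 1\] on all off-diagonal entries.
#' @return An `n_nodes` x `n_nodes` covariance matrix with a `modules`
#'   attribute giving each node's block index.
#' @export
build_block_covariance <- function(n_nodes, n_modules, rho_within,
                                   rho_between, coupling) {
  stopifnot(n_nodes >= 1, n_modules >= 1, n_modules <= n_nodes)
  if (rho_within < 0 || rho_within >= 1) stop("rho_within must lie in [0, 1)")
  if (rho_between < 0 || rho_between > rho_within)
    stop("rho_between must lie in [0, rho_within]")
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  modules <- sort(rep_len(seq_len(n_modules), n_nodes))
  sigma <- matrix(coupling * rho_between, n_nodes, n_nodes)
  same <- outer(modules, modules, "==")
  sigma[same] <- coupling * rho_within
  diag(sigma) <- 1
  ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8)
    stop("covariance is not positive semi-definite (min eigenvalue ",
         signif(ev_min, 3), ")")
  attr(sigma, "modules") <- modules
  sigma
}

#' Sample one subject's node time series
#'
#' Draws `n_volumes` independent samples from a zero-mean multivariate
#' normal with the given covariance and adds i.i.d. Gaussian observation
#' noise. The result is deterministic given `seed`.
#'
#' @param covariance Positive semi-definite N x N matrix.
#' @param n_volumes Number of time points (at least 3, so downstream
#'   correlations are defined).
#' @param noise_sd Observation-noise standard deviation.
#' @param seed Optional integer seed; when NULL the current RNG stream is
#'   used.
#' @return N x `n_volumes` numeric matrix (nodes as rows).
#' @export
sample_subject <- function(covariance, n_volumes, noise_sd = 0, seed = NULL) {
  stopifnot(is.matrix(covariance), nrow(covariance) == ncol(covariance))
  if (n_volumes < 3) stop("n_volumes must be at least 3")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  draw <- function() {
    n <- nrow(covariance)
    ts <- t(MASS::mvrnorm(n_volumes, mu = rep(0, n), Sigma = covariance))
    if (noise_sd > 0) ts <- ts + matrix(rnorm(n * n_volumes, sd = noise_sd),
                                        n, n_volumes)
    ts
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

sample_categorical <- function(n, probs) {
  # probs: named or unnamed probability vector
  idx <- sample.int(length(probs), n, replace = TRUE, prob = probs)
  if (!is.null(names(probs))) names(probs)[idx] else idx
}

#' Generate a synthetic two-group cohort
#'
#' Samples `n_good + n_poor` subjects: time series from the group-specific
#' block covariance (good outcome uses `coupling_good`, poor
#' `coupling_poor`), EEG categories and guideline predictors from
#' outcome-conditional distributions, and clinical covariates from the
#' configured group distributions. The whole cohort is a pure function of
#' the config (including its seed).
#'
#' @param config A [cohort_config()].
#' @return Object of class `comanet_cohort`: list with `subjects` (list of
#'   subject records, each holding `subject_id` and `timeseries`),
#'   `metadata` (one row per subject: outcome, EEG category, covariates,
#'   guideline predictors), and the `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_good + config$n_poor
  outcome <- rep(c("good", "poor"), c(config$n_good, config$n_poor))
  group_coupling <- ifelse(outcome == "good", config$coupling_good,
                           config$coupling_poor)

  withr::with_seed(config$seed, {
    subject_seed <- sample.int(.Machine$integer.max - 1L, n)
    coupling <- if (config$coupling_sd_logit > 0)
      stats::plogis(stats::qlogis(group_coupling) +
                      rnorm(n, sd = config$coupling_sd_logit))
    else group_coupling
    eeg_category <- integer(n)
    eeg_guideline <- character(n)
    pupils <- logical(n)
    arrest_to_mri_h <- numeric(n)
    comatose <- logical(n)
    for (g in c("good", "poor")) {
      i <- which(outcome == g)
      eeg_category[i] <- sample_categorical(length(i),
                                            unname(config$eeg_probs[g, ]))
      eeg_guideline[i] <- sample_categorical(length(i),
                                             config$guideline_eeg_probs[g, ])
      pupils[i] <- runif(length(i)) < config$pupils_ssep_prob[[g]]
      arrest_to_mri_h[i] <- rnorm(length(i),
                                  mean = config$arrest_to_mri[[g]][1],
                                  sd = config$arrest_to_mri[[g]][2])
      comatose[i] <- runif(length(i)) < config$comatose_prob[[g]]
    }
    hospital <- paste0("site", sample.int(config$n_hospitals, n,
                                          replace = TRUE))
  })

  metadata <- data.frame(
    subject_id = sprintf("sub%03d", seq_len(n)),
    outcome = outcome,
    eeg_category = eeg_category,
    eeg_category_label = eeg_category_labels[eeg_category],
    arrest_to_mri_h = arrest_to_mri_h,
    hospital = hospital,
    comatose = comatose,
    pupils_ssep_absent = pupils,
    eeg_guideline = eeg_guideline,
    coupling = coupling,
    stringsAsFactors = FALSE
  )

  subjects <- lapply(seq_len(n), function(i) {
    sigma_i <- build_block_covariance(config$n_nodes, config$n_modules,
                                      config$rho_within, config$rho_between,
                                      coupling[i])
    list(
      subject_id = metadata$subject_id[i],
      timeseries = sample_subject(sigma_i, config$n_volumes,
                                  config$noise_sd, seed = subject_seed[i])
    )
  })

  structure(list(subjects = subjects, metadata = metadata, config = config),
            class = "comanet_cohort")
}

#' @export
print.comanet_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$subjects), "subjects (",
      x$config$n_good, "good /", x$config$n_poor, "poor ),",
      x$config$n_nodes, "nodes x", x$config$n_volumes, "volumes\n")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one tab-delimited time-series table per subject (nodes as rows),
#' a cohort metadata CSV, and the resolved config as YAML.
#'
#' @param cohort A `comanet_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ts_paths <- vapply(cohort$subjects, function(s) {
    p <- file.path(dir, paste0(s$subject_id, "_timeseries.tsv"))
    write_subject_table(s$timeseries, p)
    p
  }, character(1))
  meta_path <- file.path(dir, "metadata.csv")
  write.csv(cohort$metadata, meta_path, row.names = FALSE)
  cfg_path <- file.path(dir, "config.yaml")
  write_config(cohort$config, cfg_path)
  invisible(list(timeseries = ts_paths, metadata = meta_path,
                 config = cfg_path))
}
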