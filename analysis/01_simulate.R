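#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic cohort at the default study conditions
# (44 good / 26 poor outcome, 264 nodes, 220 volumes) and write one
# time-series table per subject plus the cohort metadata.
#
# Subject-level data are large and go under scratch/; summary tables and
# the resolved configuration go under results/.

suppressPackageStartupMessages(library(comanet))

seed <- 1L
cohort_dir <- "scratch/cohort"
dir.create("results", showWarnings = FALSE)

cfg <- cohort_config(seed = seed)
cat(sprintf("Simulating %d + %d subjects, %d nodes x %d volumes (seed %d)\n",
            cfg$n_good, cfg$n_poor, cfg$n_nodes, cfg$n_volumes, seed))

cohort <- generate_cohort(cfg)
paths <- write_cohort(cohort, cohort_dir)
write_config(cfg, "results/cohort_config.yaml")

md <- cohort$metadata
cat(sprintf("Wrote %d time-series tables to %s\n",
            length(paths$timeseries), cohort_dir))
cat("EEG categories by outcome:\n")
print(table(md$outcome, md$eeg_category_label))
cat("Guideline predictors by outcome:\n")
print(table(md$outcome, md$eeg_guideline))
print(table(md$outcome, md$pupils_ssep_absent))
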