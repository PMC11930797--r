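#!/usr/bin/env Rscript
# Stage 2: per-subject Fisher-z connectivity matrices from the simulated
# time series. The first 5 volumes are discarded (steady state); Pearson
# correlations are Fisher z-transformed and negative edges zeroed.
# Writes each matrix under scratch/connectivity and a whole-brain FC
# summary to results/whole_brain_fc.csv.

suppressPackageStartupMessages(library(comanet))

cohort_dir <- "scratch/cohort"
conn_dir <- "scratch/connectivity"
dir.create(conn_dir, recursive = TRUE, showWarnings = FALSE)

md <- read_cohort_metadata(file.path(cohort_dir, "metadata.csv"))
cat(sprintf("Computing connectivity for %d subjects\n", nrow(md)))

fc <- vapply(md$subject_id, function(id) {
  ts <- read_subject_table(file.path(cohort_dir,
                                     paste0(id, "_timeseries.tsv")))
  conn <- subject_connectivity(ts, discard_first_k = 5)
  write_connectivity(conn, file.path(conn_dir, paste0(id, "_conn.tsv")))
  whole_brain_fc(conn)
}, numeric(1))

out <- data.frame(subject_id = md$subject_id, whole_brain_fc = fc)
write.csv(out, "results/whole_brain_fc.csv", row.names = FALSE)

good <- md$outcome == "good"
cat(sprintf("Median whole-brain FC: good %.3f, poor %.3f\n",
            median(fc[good]), median(fc[!good])))
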