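#!/usr/bin/env Rscript
# Stage 5: prognostic model comparison. Fits the guideline logistic
# model (pupils/SSEP indicator + guideline EEG class), each graph
# measure alone, and the guideline model augmented with each measure;
# reports apparent AUC, sensitivity for good outcome at specificity
# >= 90%, sensitivity for poor outcome at specificity 100%, and the
# likelihood-ratio test of each augmented model against the guideline
# model.

suppressPackageStartupMessages(library(comanet))

md <- read_cohort_metadata("scratch/cohort/metadata.csv")
metrics <- read.csv("results/metrics.csv")
stopifnot(identical(md$subject_id, metrics$subject_id))

cmp <- suppressWarnings(compare_prediction_models(md, metrics))
write.csv(cmp, "results/prediction.csv", row.names = FALSE)

cat("Prognostic model comparison (apparent, in-sample):\n")
print(transform(cmp,
                auc = round(auc, 3), sens_good = round(sens_good, 3),
                sens_poor = round(sens_poor, 3),
                loglik = round(loglik, 2),
                lrt_p = signif(lrt_p, 3)),
      row.names = FALSE)

guide <- cmp[cmp$model_label == "guideline", ]
aug <- cmp[grepl("^guideline\\+", cmp$model_label), ]
cat(sprintf("\nGuideline model: AUC %.3f, sens(good)@spec>=0.90 = %.2f, sens(poor)@spec=1 = %.2f\n",
            guide$auc, guide$sens_good, guide$sens_poor))
cat(sprintf("Augmented models: AUC %.3f-%.3f; best sens(good) %.2f; best sens(poor) %.2f\n",
            min(aug$auc), max(aug$auc), max(aug$sens_good),
            max(aug$sens_poor)))
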