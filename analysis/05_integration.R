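#!/usr/bin/env Rscript

# Integration: simulates longitudinal six-metric trajectories for the
# 11-patient cohort, labels timepoints (baseline and at-/post-relapse
# positive), fits the mixed-effect logistic model with patient-grouped
# 10-fold (capped) cross-validation, normalizes integrated probabilities
# to the cohort baseline, and compares per-metric univariate models.

suppressPackageStartupMessages(library(cfMRD))
dir.create("results", showWarnings = FALSE)
seed <- 3L

fx <- make_clinical_fixture()
ts <- simulate_metric_timeseries(fx, seed = seed)
sc <- scale_metrics(ts$metrics)
fit <- suppressWarnings(fit_integration_model(sc, ts$labels, seed = seed))
sco <- normalize_to_baseline(fit)

cat("Eligible patients:", nrow(fit$folds), "; CV accuracy:",
    round(fit$cv_accuracy, 3), "\n")
cat("Fixed-effect coefficients:\n")
print(round(fit$coefficients, 2))
cat("Random-intercept variance:", round(fit$random_intercept_var, 3), "\n")
cat("Mean baseline-normalized score by group at final timepoint:\n")
final <- do.call(rbind, lapply(split(sco, sco$patient_id),
                               function(d) d[which.max(d$month), ]))
grp <- fx$records$relapse[match(final$patient_id, fx$records$patient_id)]
print(tapply(final$score, grp, mean))

u <- suppressWarnings(univariate_significance(sc, ts$labels))
cat("Univariate mixed-model LRT p-values:\n")
print(u, row.names = FALSE)

write.table(sco, "results/integrated_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(u, "results/univariate_models.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
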