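#!/usr/bin/env Rscript

# Methylome arm of the pipeline: (1) builds the tumor-specific
# hypermethylation signature from simulated cohort-labelled array
# matrices via pairwise differential analysis and the >21-of-33 vote
# rule; (2) fits the two-component NB mixture methylation caller on
# simulated cfMeDIP windows and scores tumor-like vs healthy-like samples
# over the signature bins.

suppressPackageStartupMessages(library(cfMRD))
dir.create("results", showWarnings = FALSE)
seed <- 40L

## 1. signature from array matrices ----------------------------------------
sim <- simulate_methylation_arrays(n_cohorts = 34, n_samples_per_cohort = 50,
                                   n_sites = 10080, planted = 1:80,
                                   effect_size = 4, seed = seed)
m <- mvalues(sim$beta)
idx <- split(seq_along(sim$labels), sim$labels)
sig <- build_signature(
  m[, idx$cohort1],
  lapply(paste0("cohort", 2:34), function(cn) m[, idx[[cn]]]),
  lfc_min = 2, alpha = 0.05, vote_min = 21, seed = seed)
recovered <- sort(match(sig$sites, rownames(sim$beta)))
cat("Signature:", length(sig$sites), "sites; planted recovered exactly:",
    identical(recovered, 1:80), "\n")

sig_tab <- data.frame(site = sig$sites,
                      votes = sig$votes[sig$sites])
write.table(sig_tab, "results/methylation_signature.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## 2. methylation caller + per-sample scores -------------------------------
g <- genome_model("chr1", 8000 * 300 + 150)
w <- build_windows(g, 300)
sig_idx <- which(w$cpg >= 5)[seq_len(77)]
sig_bins <- paste0(w$chrom[sig_idx], ":",
                   format(w$start[sig_idx], scientific = FALSE, trim = TRUE))

score_sample <- function(s, tumor) {
  truth <- methylation_truth(pi = if (tumor) 0.25 else 0.1)
  smp <- simulate_medip_windows(g, truth, seed = s, windows = w)
  if (tumor) {
    # tumor sample: signature bins drawn from the methylated component
    smp$windows$count[sig_idx] <- withr::with_seed(s + 1,
      rnbinom(77, size = 8, mu = exp(3 + 0.08 * w$cpg[sig_idx])))
  }
  fit <- em_fit(smp$windows, fit_nonmethylated(smp$windows), tol = 1e-4)
  methylation_score(fit, sig_bins)
}

healthy_scores <- vapply(seed + 1:6, function(s) score_sample(s, FALSE), numeric(1))
tumor_scores <- vapply(seed + 100 + 1:4, function(s) score_sample(s, TRUE), numeric(1))
thr <- healthy_threshold_classify(0, healthy_scores)$threshold

cat("Healthy methylation scores:", paste(round(healthy_scores, 1), collapse = ", "), "\n")
cat("Tumor methylation scores:  ", paste(round(tumor_scores, 1), collapse = ", "), "\n")
cat("Healthy 90th percentile threshold:", round(thr, 2),
    "; tumors above threshold:", sum(tumor_scores > thr), "/", length(tumor_scores), "\n")

write.table(
  data.frame(sample = c(paste0("healthy_", seq_along(healthy_scores)),
                        paste0("tumor_", seq_along(tumor_scores))),
             methylation_score = c(healthy_scores, tumor_scores),
             positive = c(healthy_scores, tumor_scores) > thr),
  "results/methylation_scores.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
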