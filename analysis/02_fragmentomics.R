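#!/usr/bin/env Rscript

# Fragmentomic metrics on a synthetic monitoring cohort: global short-
# fragment proportions, 90-150 bp size z-scores, genome-wide and
# targeted-locus ratio z-scores against a simulated healthy panel.
# A tumor-shifted sample carries more sub-nucleosomal fragments; every
# metric is expressed relative to the healthy controls' 90th percentile.

suppressPackageStartupMessages(library(cfMRD))
dir.create("results", showWarnings = FALSE)
seed <- 20L

g <- genome_model(c("chr3", "chr6", "chr8"), c(2e7, 2e7, 2e7))
n_healthy <- 12

healthy_frags <- lapply(seq_len(n_healthy), function(i)
  simulate_fragments(fragment_length_model(n_fragments = 1e5), g, seed = seed + i))

# tumor-shifted samples: rising short-fragment weight
shift <- c(0.12, 0.18, 0.25, 0.35)
tumor_frags <- lapply(seq_along(shift), function(i)
  simulate_fragments(
    fragment_length_model(data.frame(mean = c(120, 167), sd = c(15, 20),
                                     weight = c(shift[i], 1 - shift[i])),
                          n_fragments = 1e5),
    g, seed = seed + 100 + i))

size_feature <- function(frag) {
  d <- size_distribution(frag)
  p <- d$count / d$total
  names(p) <- as.character(d$length)
  p[as.character(90:150)]
}
size_panel <- build_healthy_panel(lapply(healthy_frags, size_feature))

ratio_feature <- function(frag) {
  prof <- suppressWarnings(fragment_ratio_profile(frag, g))
  v <- prof$bins5$ratio_scaled
  names(v) <- prof$bins5$bin_id
  list(profile = prof, v5 = v[!is.na(v)])
}
healthy_profiles <- lapply(healthy_frags, ratio_feature)
ratio_panel <- build_healthy_panel(lapply(healthy_profiles, `[[`, "v5"))

rows <- list()
for (i in seq_along(tumor_frags)) {
  frag <- tumor_frags[[i]]
  sz <- size_zscore(size_distribution(frag), size_panel)
  prof <- suppressWarnings(fragment_ratio_profile(frag, g))
  rz <- profile_zscore(prof, ratio_panel)
  rows[[i]] <- data.frame(
    sample = paste0("tumor_shift_", shift[i]),
    short_fragment_proportion = short_fragment_proportion(size_distribution(frag)),
    size_z = sz$aggregate, ratio_z = rz$aggregate)
}
for (i in seq_along(healthy_frags)) {
  frag <- healthy_frags[[i]]
  rows[[length(rows) + 1]] <- data.frame(
    sample = paste0("healthy_", i),
    short_fragment_proportion = short_fragment_proportion(size_distribution(frag)),
    size_z = size_zscore(size_distribution(frag), size_panel)$aggregate,
    ratio_z = profile_zscore(healthy_profiles[[i]]$profile, ratio_panel)$aggregate)
}
tab <- do.call(rbind, rows)
healthy_size_z <- tab$size_z[grepl("healthy", tab$sample)]
thr <- healthy_threshold_classify(0, healthy_size_z)$threshold
tab$size_positive <- tab$size_z > thr

cat("Healthy size-z 90th percentile threshold:", round(thr, 3), "\n")
cat("Short-fragment proportion rises with the planted shift:\n")
print(tab[, c("sample", "short_fragment_proportion", "size_z", "size_positive")],
      row.names = FALSE)

write.table(tab, "results/fragmentomics_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
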