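# Shared fixtures: small genomes and panel builders used across tests.
# Everything is generated in code; no binary fixtures.

# Toy genome with the three scored chromosomes (20 Mb each => 20 x 1 Mb
# bins, 200 x 100 kb bins, 4 x 5 Mb bins per chromosome).
toy_genome <- function() {
  genome_model(c("chr3", "chr6", "chr8"), c(2e7, 2e7, 2e7))
}

# Toy genome with a large neutral background chromosome so CNV events are
# a small fraction of bins (as in a real genome).
toy_genome_bg <- function() {
  genome_model(c("chr1", "chr3", "chr6", "chr8"), c(1.2e8, 2e7, 2e7, 2e7))
}

# Single-chromosome genome holding ~n 300 bp windows for methylation sims.
medip_genome <- function(n_windows = 20000) {
  genome_model("chr1", n_windows * 300 + 150)
}

# Healthy binned-count sample: GC-corrected and median-normalized, as a
# named feature vector keyed by bin id.
healthy_count_features <- function(genome, seed, depth = 1000, width = 1e6) {
  b <- simulate_cnv_counts(genome, NULL, depth = depth, seed = seed, width = width)
  b <- suppressWarnings(gc_correct_counts(b))
  v <- b$count_corr / stats::median(b$count_corr)
  names(v) <- paste0(b$chrom, ":", format(b$start, scientific = FALSE, trim = TRUE))
  v
}

# Count panel + derived log2-ratio panel from healthy seeds.
healthy_cn_panels <- function(genome, seeds, depth = 1000, width = 1e6) {
  counts <- lapply(seeds, function(s) healthy_count_features(genome, s, depth, width))
  names(counts) <- paste0("h", seq_along(seeds))
  count_panel <- build_healthy_panel(counts)
  ratios <- lapply(counts, function(v) {
    med <- count_panel$median[names(v)]
    ok <- v > 0 & med > 0
    log2(v[ok] / med[ok])
  })
  list(counts = count_panel, ratios = build_healthy_panel(ratios),
       count_samples = counts)
}

# CN weighted score for one GC-corrected sample against the panels.
cn_weighted_score <- function(bins, panels) {
  cn_zscore(copy_ratio(bins, panels$counts), panels$ratios)$weighted_score
}

# Healthy fragment-length model (mono-nucleosome dominant) and a
# tumor-shifted variant with extra short-fragment mass.
healthy_length_model <- function(n = 1e5) {
  fragment_length_model(n_fragments = n)
}

tumor_length_model <- function(short_weight = 0.3, n = 1e5) {
  fragment_length_model(
    components = data.frame(mean = c(120, 167), sd = c(15, 20),
                            weight = c(short_weight, 1 - short_weight)),
    n_fragments = n
  )
}
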