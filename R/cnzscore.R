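# Copy-number signal from binned sWGS counts: GC correction, log-ratio vs
# a healthy panel, arm-weighted z-scores on chromosomes 3/6/8, the
# short-fragment mode gate, and the tumor-fraction positivity rule.

#' GC-correct binned counts
#'
#' Additive loess correction (span 3/4): `corrected = raw - fitted + grand
#' mean`, computed over unmasked bins; negative corrected counts are
#' clipped to 0 and flagged. Constant GC degenerates to the identity with a
#' warning.
#'
#' @param bins Data.frame with `count`, `gc`, and optionally `excluded`.
#' @param span Loess span (default 3/4).
#' @param min_bins Minimum unmasked bins required (default 50).
#' @return The input with `count_corr` and `clipped` columns added.
#' @export
gc_correct_counts <- function(bins, span = 0.75, min_bins = 50L) {
  mask <- if ("excluded" %in% names(bins)) bins$excluded else rep(FALSE, nrow(bins))
  if (sum(!mask) < min_bins) {
    stop_data("need at least ", min_bins, " unmasked bins for GC correction")
  }
  corr <- rep(NA_real_, nrow(bins))
  corr[!mask] <- loess_gc_correct(bins$count[!mask], bins$gc[!mask], span)
  bins$clipped <- !is.na(corr) & corr < 0
  corr[bins$clipped] <- 0
  bins$count_corr <- corr
  bins
}

# Depth-normalize corrected counts to median 1 over unmasked bins. The
# median (not the mean) is used so that large copy-number events do not
# drag the normalizer and bias unaffected bins.
normalize_depth <- function(counts) {
  m <- stats::median(counts, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) stop_data("cannot depth-normalize: median bin count is zero")
  counts / m
}

#' Per-bin copy ratio against a healthy panel
#'
#' `log2(sample / panel median)` per bin, after both sides are GC-corrected
#' and depth-normalized to their median bin (so uniform depth scaling of
#' the sample cancels and large CNV events do not bias the normalizer).
#' Bins with panel median <= 0 or sample count <= 0 are masked.
#'
#' @param bins GC-corrected sample bins (from [gc_correct_counts()]), with
#'   `arm` and bin coordinates.
#' @param panel Healthy panel of GC-corrected, depth-normalized counts with
#'   features keyed by `bin_id`.
#' @return An object of class `copy_ratio_profile`: data.frame with
#'   `bin_id`, `arm`, `log2_ratio`, `masked`.
#' @export
copy_ratio <- function(bins, panel) {
  bins$bin_id <- window_id(bins$chrom, bins$start)
  idx <- match(bins$bin_id, panel$features)
  if (anyNA(idx)) stop_data("sample bins not covered by the panel")
  norm <- normalize_depth(bins$count_corr)
  med <- panel$median[idx]
  masked <- is.na(norm) | norm <= 0 | med <= 0
  if (all(masked)) stop_data("all bins masked in copy_ratio")
  out <- data.frame(
    bin_id = bins$bin_id, chrom = bins$chrom, start = bins$start,
    arm = bins$arm,
    log2_ratio = ifelse(masked, NA_real_, log2(norm / med)),
    masked = masked, stringsAsFactors = FALSE
  )
  class(out) <- c("copy_ratio_profile", "data.frame")
  out
}

#' Arm-weighted copy-number z-score over chromosomes 3, 6 and 8
#'
#' Per-bin z-scores of the log2 ratios against a healthy panel of the same
#' ratios, restricted to the named chromosomes. Each arm aggregates as
#' `|sum(z) / sqrt(n_arm)|` (absolute value, so losses and gains both
#' elevate the score) and the genome score is the bin-count-weighted sum
#' `sum(w_a * |aggregate_a|)` with `w_a = n_a / sum(n_a)`. Arms with no
#' usable bins are dropped and the weights renormalized.
#'
#' @param ratio A [copy_ratio()] profile.
#' @param panel Healthy panel of per-bin log2 ratios (features = `bin_id`).
#' @param chroms Chromosomes to score (default `c("chr3", "chr6", "chr8")`).
#' @return An object of class `cn_zscore`: list with per-bin `z`, per-arm
#'   table (`arm`, `n`, `aggregate`, `weight`), and `weighted_score`.
#' @export
cn_zscore <- function(ratio, panel, chroms = c("chr3", "chr6", "chr8")) {
  keep <- ratio$chrom %in% chroms & !ratio$masked
  sub <- ratio[keep, , drop = FALSE]
  if (!nrow(sub)) stop_data("no usable bins on the requested chromosomes")
  feats <- intersect(sub$bin_id, panel$features[!panel$flagged])
  sub <- sub[sub$bin_id %in% feats, , drop = FALSE]
  if (!nrow(sub)) stop_data("all requested bins flagged in the panel")
  z <- (sub$log2_ratio - panel$mean[sub$bin_id]) / panel$sd[sub$bin_id]
  arm_key <- paste0(sub$chrom, sub$arm)
  arms <- sort(unique(arm_key))
  agg <- vapply(arms, function(a) {
    za <- z[arm_key == a]
    abs(sum(za) / sqrt(length(za)))
  }, numeric(1))
  n_a <- vapply(arms, function(a) sum(arm_key == a), numeric(1))
  w <- n_a / sum(n_a)
  structure(
    list(z = stats::setNames(z, sub$bin_id),
         arms = data.frame(arm = arms, n = n_a, aggregate = agg, weight = w,
                           row.names = NULL, stringsAsFactors = FALSE),
         weighted_score = sum(w * agg)),
    class = "cn_zscore"
  )
}

#' @export
print.cn_zscore <- function(x, ...) {
  cat("cn_zscore: weighted score =", signif(x$weighted_score, 4), "over",
      nrow(x$arms), "arms\n")
  invisible(x)
}

#' Tumor-fraction positivity rule
#'
#' A predicted tumor fraction is called positive only when it strictly
#' exceeds 0.03 (the detection limit used for copy-number-based ctDNA
#' calls); 0.03 itself is negative.
#'
#' @param tf Tumor fraction(s) in `[0, 1]`.
#' @param threshold Positivity threshold (default 0.03, strict).
#' @return Logical vector.
#' @export
classify_tumor_fraction <- function(tf, threshold = 0.03) {
  if (any(!is.finite(tf)) || any(tf < 0 | tf > 1)) {
    stop_data("tumor fraction must lie in [0, 1]")
  }
  tf > threshold
}

#' Short-fragment mode with the coverage gate
#'
#' Filters to 90-150 bp fragments and computes the residual mean coverage
#' `sum(lengths) / genome length`. When coverage after pruning is <= the
#' threshold (default 0.1X) the analysis is refused — an explicit status,
#' not an error — because the copy-number statistics are unreliable at that
#' depth.
#'
#' @param frag A [fragment_set()].
#' @param genome A [genome_model()].
#' @param coverage_threshold Minimum post-pruning coverage (default 0.1).
#' @param lo,hi Short band (default 90-150 bp).
#' @return A list with `status` ("ok" or "refused"), `coverage`, and (when
#'   ok) the pruned `fragments`.
#' @export
short_fragment_mode <- function(frag, genome, coverage_threshold = 0.1,
                                lo = 90, hi = 150) {
  short <- filter_by_length(frag, lo, hi)
  coverage <- sum(short$end - short$start) / genome_total_length(genome)
  if (coverage <= coverage_threshold) {
    return(list(status = "refused", coverage = coverage, fragments = NULL))
  }
  list(status = "ok", coverage = coverage, fragments = short)
}
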