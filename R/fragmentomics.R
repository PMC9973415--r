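# Fragmentomic metrics: size distributions, DELFI-style ratio profiles,
# targeted-locus ratios, and site-centered coverage, all reduced to
# z-scores against a healthy panel.

#' Proportion of short cfDNA fragments
#'
#' The fraction of fragments in the 10-150 bp band among all fragments in
#' the 10-250 bp band — a global, depth-invariant measure of
#' tumor-associated fragment shortening.
#'
#' @param dist A [size_distribution()].
#' @param short Closed short band (default 10-150 bp).
#' @param all Closed denominator band (default 10-250 bp).
#' @return A proportion in `[0, 1]`.
#' @export
short_fragment_proportion <- function(dist, short = c(10, 150),
                                      all = c(10, 250)) {
  in_band <- function(b) sum(dist$count[dist$length >= b[1] & dist$length <= b[2]])
  den <- in_band(all)
  if (den == 0) stop_data("no fragments in the denominator band")
  in_band(short) / den
}

# Per-length proportions of a size distribution (over its full range).
size_proportions <- function(dist) {
  if (dist$total == 0) stop_data("empty size distribution")
  p <- dist$count / dist$total
  names(p) <- as.character(dist$length)
  p
}

#' Fragment-size z-score against a healthy panel
#'
#' Converts the distribution to per-length proportions, z-scores each
#' length in `lengths` (default 90-150 bp, the tumor-shifted band) against
#' the panel, and aggregates per [zscore_summary()].
#'
#' @param dist A [size_distribution()].
#' @param panel Healthy panel over per-length proportions (features named
#'   by fragment length).
#' @param lengths Integer lengths to score (default `90:150`).
#' @return A [zscore_summary()].
#' @export
size_zscore <- function(dist, panel, lengths = 90:150) {
  p <- size_proportions(dist)
  want <- as.character(lengths)
  missing <- setdiff(intersect(want, panel$features), names(p))
  if (length(missing)) stop_data("distribution does not cover panel lengths")
  sub <- subset_panel(panel, intersect(want, panel$features))
  zscore_summary(p[sub$features], sub)
}

# Restrict a panel to a feature subset (keeps flags and values).
subset_panel <- function(panel, features) {
  missing <- setdiff(features, panel$features)
  if (length(missing)) {
    stop_data("panel missing features: ",
              paste(utils::head(missing, 10), collapse = ", "))
  }
  structure(
    list(features = features,
         mean = panel$mean[features], sd = panel$sd[features],
         median = panel$median[features],
         flagged = panel$flagged[features],
         n_samples = panel$n_samples,
         values = panel$values[features, , drop = FALSE]),
    class = "healthy_panel"
  )
}

# Additive loess GC correction: raw - fitted + grand mean. Falls back to
# identity (with a warning) when the fit is degenerate.
loess_gc_correct <- function(count, gc, span = 0.75) {
  if (length(unique(gc)) < 5L || stats::sd(gc) < 1e-12) {
    warning("GC nearly constant; correction is identity")
    return(count)
  }
  fit <- tryCatch(
    stats::loess(count ~ gc, span = span,
                 control = stats::loess.control(surface = "direct")),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("loess fit failed; correction is identity")
    return(count)
  }
  count - stats::predict(fit, gc) + mean(count)
}

#' DELFI-adapted fragment ratio profile
#'
#' Counts short (90-150 bp) and long (151-220 bp) fragments in 100 kb bins,
#' corrects each class for GC with additive loess (span 3/4, `raw - fitted
#' + grand mean`), aggregates corrected counts into 5 Mb bins, forms the
#' short/long ratio, and scales ratios to mean 0, unit SD. Blacklisted 100
#' kb bins are excluded before correction; 5 Mb bins whose corrected long
#' count is <= 0 are masked. Per-100 kb scaled ratios are retained for
#' targeted-locus analyses.
#'
#' @param frag A [fragment_set()].
#' @param genome A [genome_model()].
#' @param span Loess span (default 3/4).
#' @param width_small,width_large Bin widths (defaults 100 kb and 5 Mb).
#' @return An object of class `ratio_profile` with `bins100` (per-100 kb
#'   corrected counts and scaled ratios) and `bins5` (per-5 Mb scaled
#'   ratios).
#' @export
fragment_ratio_profile <- function(frag, genome, span = 0.75,
                                   width_small = 1e5, width_large = 5e6) {
  bc <- bin_fragment_counts(frag, genome, width_small,
                            length_classes = list(short = c(90, 150),
                                                  long = c(151, 220)))
  bins <- bc$bins[!bc$bins$excluded, , drop = FALSE]
  if (!nrow(bins)) stop_data("all bins blacklisted")
  bins$short_corr <- loess_gc_correct(bins$short, bins$gc, span)
  bins$long_corr <- loess_gc_correct(bins$long, bins$gc, span)

  # per-100 kb ratio (for targeted analyses)
  bins$ratio <- ifelse(bins$long_corr > 0, bins$short_corr / bins$long_corr, NA_real_)
  bins$ratio_scaled <- scale_to_unit(bins$ratio)
  bins$bin_id <- window_id(bins$chrom, bins$start)

  # aggregate into 5 Mb bins (drop 100 kb bins past the last full 5 Mb bin)
  group <- floor(bins$start / width_large)
  chrom_len <- genome$chroms$length[genome_chrom_index(genome, bins$chrom)]
  full <- (group + 1) * width_large <= chrom_len
  agg <- stats::aggregate(
    cbind(short_corr, long_corr) ~ chrom + group,
    data = cbind(bins[full, c("chrom", "short_corr", "long_corr")],
                 group = group[full]),
    FUN = sum
  )
  agg$start <- agg$group * width_large
  agg$ratio <- ifelse(agg$long_corr > 0, agg$short_corr / agg$long_corr, NA_real_)
  if (all(is.na(agg$ratio))) stop_data("all 5 Mb bins masked (no long fragments)")
  agg$ratio_scaled <- scale_to_unit(agg$ratio)
  agg$bin_id <- window_id(agg$chrom, agg$start)
  ord <- order(match(agg$chrom, genome$chroms$chrom), agg$start)
  agg <- agg[ord, c("chrom", "start", "short_corr", "long_corr",
                    "ratio", "ratio_scaled", "bin_id")]
  rownames(agg) <- NULL
  structure(list(bins100 = bins, bins5 = agg, span = span),
            class = "ratio_profile")
}

# Scale to mean 0, unit SD over non-NA entries; all-zero with a warning
# when the SD is degenerate.
scale_to_unit <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  s <- stats::sd(x[ok])
  if (!is.finite(s) || s < 1e-12) {
    warning("degenerate SD; scaled values set to 0")
    x[ok] <- 0
    return(x)
  }
  x[ok] <- (x[ok] - mean(x[ok])) / s
  x
}

#' Genome-wide ratio-profile z-score
#'
#' Binwise z-scores of the scaled 5 Mb ratios against a healthy panel,
#' aggregated per [zscore_summary()].
#'
#' @param profile A [fragment_ratio_profile()].
#' @param panel Healthy panel over 5 Mb `bin_id` features.
#' @return A [zscore_summary()].
#' @export
profile_zscore <- function(profile, panel) {
  v <- profile$bins5$ratio_scaled
  names(v) <- profile$bins5$bin_id
  v <- v[!is.na(v)]
  zscore_summary(v, subset_panel(panel, intersect(panel$features, names(v))))
}

#' Targeted-locus ratio z-score
#'
#' Restricts the per-100 kb scaled ratios to bins overlapping at least one
#' supplied locus (any overlap, >= 1 bp) and recomputes the z-score
#' aggregate over that bin subset only — e.g. fragment ratios at PRC1
#' binding sites.
#'
#' @param profile A [fragment_ratio_profile()].
#' @param loci Data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param panel Healthy panel over 100 kb `bin_id` features.
#' @return A [zscore_summary()] over the selected bins.
#' @export
targeted_profile_zscore <- function(profile, loci, panel) {
  if (is.null(loci) || nrow(loci) == 0L) stop_config("loci must be nonempty")
  bins <- profile$bins100
  sel <- rep(FALSE, nrow(bins))
  for (ch in unique(loci$chrom)) {
    bi <- which(bins$chrom == ch)
    if (!length(bi)) next
    l <- loci[loci$chrom == ch, , drop = FALSE]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = bins$start[bi] + 1L, end = bins$end[bi]),
      IRanges::IRanges(start = l$start + 1L, end = l$end)
    )
    sel[bi[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  sel <- sel & !is.na(bins$ratio_scaled)
  if (!any(sel)) stop_data("no 100 kb bins overlap the loci")
  v <- bins$ratio_scaled[sel]
  names(v) <- bins$bin_id[sel]
  zscore_summary(v, subset_panel(panel, intersect(panel$features, names(v))))
}

#' Composite coverage around site centers
#'
#' For every offset in `-flank..flank`, counts the fragments overlapping
#' `center + offset`, summed over sites, then normalizes so the mean depth
#' over the outer flanks (|offset| in 750-1000 bp) equals 1. The central
#' coverage is the mean normalized depth over |offset| <= 30 bp; open
#' chromatin at the sites (tissue signal) depresses it below the flank
#' level.
#'
#' @param frag A [fragment_set()].
#' @param sites Data.frame with `chrom` and `center` positions.
#' @param flank Half-window in bp (default 1000).
#' @param central_halfwidth Central window half-width (default 30 bp).
#' @param flank_norm Offsets used for normalization (default 750-1000 bp).
#' @return An object of class `coverage_profile` with `offset`, `depth`
#'   (normalized), `central`, `n_sites`.
#' @export
site_coverage <- function(frag, sites, flank = 1000, central_halfwidth = 30,
                          flank_norm = c(750, 1000)) {
  if (is.null(sites) || nrow(sites) == 0L) stop_config("need at least one site")
  offsets <- seq.int(-flank, flank)
  depth <- numeric(length(offsets))
  for (ch in unique(sites$chrom)) {
    f <- frag[frag$chrom == ch, , drop = FALSE]
    centers <- sites$center[sites$chrom == ch]
    if (!nrow(f)) next
    for (ctr in centers) {
      lo <- pmax(f$start - ctr, -flank)
      hi <- pmin(f$end - 1 - ctr, flank)
      keep <- which(hi >= lo & hi >= -flank & lo <= flank)
      if (!length(keep)) next
      # difference-array accumulation of interval cover counts
      d <- numeric(length(offsets) + 1L)
      i1 <- lo[keep] + flank + 1L
      i2 <- hi[keep] + flank + 2L
      for (j in seq_along(keep)) {
        d[i1[j]] <- d[i1[j]] + 1
        d[i2[j]] <- d[i2[j]] - 1
      }
      depth <- depth + cumsum(d[seq_along(offsets)])
    }
  }
  flank_mean <- mean(depth[abs(offsets) >= flank_norm[1] &
                           abs(offsets) <= flank_norm[2]])
  if (flank_mean <= 0) stop_data("zero coverage in the normalization flanks")
  norm <- depth / flank_mean
  structure(
    list(offset = offsets, depth = norm,
         central = mean(norm[abs(offsets) <= central_halfwidth]),
         n_sites = nrow(sites)),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile:", x$n_sites, "sites; central coverage =",
      signif(x$central, 4), "\n")
  invisible(x)
}

#' Central-coverage z-score
#'
#' `z = (central - panel mean) / panel SD` for the +-30 bp central coverage
#' against a healthy panel built from the same site list and flank. Lower
#' coverage than healthy (more open chromatin, tissue signal) gives a
#' negative z.
#'
#' @param profile A [site_coverage()] profile (or a bare central-coverage
#'   value).
#' @param panel Healthy panel with the single feature `"central"`.
#' @return A single z value.
#' @export
central_coverage_zscore <- function(profile, panel) {
  central <- if (inherits(profile, "coverage_profile")) profile$central else profile
  if (!"central" %in% panel$features) {
    stop_data("panel must carry the 'central' feature")
  }
  if (panel$flagged["central"]) stop_data("panel central coverage has zero variance")
  unname((central - panel$mean["central"]) / panel$sd["central"])
}
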