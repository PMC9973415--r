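# Tumor-specific hypermethylation signature: pairwise differential
# analysis of cohort-labelled methylation matrices on the M-value scale,
# a cross-comparison vote rule, and mapping of selected sites to
# methylation windows.

#' Beta to M-value transform
#'
#' `M = log2(beta / (1 - beta))` after clipping betas to
#' `[1e-6, 1 - 1e-6]`; `beta_from_m()` inverts it.
#'
#' @param beta Matrix or vector of beta values in (0, 1).
#' @param m M-values.
#' @return Same shape as the input.
#' @export
mvalues <- function(beta) {
  b <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  stats::qlogis(b) / log(2)
}

#' @rdname mvalues
#' @export
beta_from_m <- function(m) stats::plogis(m * log(2))

row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Pairwise differential methylation (one comparison)
#'
#' Subsamples each cohort to `n_subsample` columns (without replacement,
#' capped at cohort size), then runs a per-site Welch two-sample t-test on
#' M-values. `logfc` is the target-minus-comparison mean difference on the
#' M scale; p-values are Benjamini-Hochberg adjusted across sites within
#' this comparison. Sites with zero variance in both groups get `p = 1`
#' and are flagged.
#'
#' @param target_m,comparison_m M-value matrices (sites x samples, same
#'   rows).
#' @param n_subsample Samples drawn per cohort (default 50).
#' @param seed Integer RNG seed for the subsampling.
#' @return A data.frame with `site`, `logfc`, `p`, `p_adj`, `flagged`.
#' @export
differential_comparison <- function(target_m, comparison_m,
                                    n_subsample = 50L, seed = 1L) {
  if (ncol(target_m) < 2L || ncol(comparison_m) < 2L) {
    stop_data("each cohort needs at least 2 samples")
  }
  if (nrow(target_m) != nrow(comparison_m)) {
    stop_data("site sets differ between cohorts")
  }
  withr_seed(seed, {
    t_cols <- sample.int(ncol(target_m), min(n_subsample, ncol(target_m)))
    c_cols <- sample.int(ncol(comparison_m), min(n_subsample, ncol(comparison_m)))
  })
  x <- target_m[, t_cols, drop = FALSE]
  y <- comparison_m[, c_cols, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- row_vars(x); v2 <- row_vars(y)
  se2 <- v1 / n1 + v2 / n2
  flagged <- se2 <= 0
  tstat <- ifelse(flagged, 0, (m1 - m2) / sqrt(se2))
  df <- ifelse(flagged, 1,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)))
  p <- ifelse(flagged, 1, 2 * stats::pt(-abs(tstat), df))
  data.frame(
    site = rownames(target_m) %||% as.character(seq_len(nrow(target_m))),
    logfc = m1 - m2,
    p = p,
    p_adj = stats::p.adjust(p, method = "BH"),
    flagged = flagged,
    stringsAsFactors = FALSE
  )
}

#' Build a tumor-specific hypermethylation signature
#'
#' For each comparison cohort, marks the sites that are hypermethylated in
#' the target (`logfc >= lfc_min`, BH-adjusted `p < alpha`, positive
#' direction). A site's vote is the number of comparisons in which it is
#' marked; the signature keeps sites with votes strictly greater than
#' `vote_min` (so exactly `vote_min` votes is excluded).
#'
#' @param target_m Target-cohort M-value matrix (sites x samples).
#' @param comparisons Named list of comparison-cohort M-value matrices.
#' @param lfc_min Minimum M-scale log fold change (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param vote_min Vote threshold, strict (default 21).
#' @param n_subsample Per-cohort subsample size (default 50).
#' @param seed Integer RNG seed; comparison `i` uses `seed + i`.
#' @return An object of class `meth_signature`: `sites` (selected ids),
#'   `votes` (named vector over all sites), and the thresholds used.
#' @export
build_signature <- function(target_m, comparisons, lfc_min = 2, alpha = 0.05,
                            vote_min = 21L, n_subsample = 50L, seed = 1L) {
  if (!length(comparisons)) stop_config("need at least one comparison cohort")
  if (vote_min >= length(comparisons)) {
    stop_config("vote_min (", vote_min, ") must be below the number of comparisons (",
                length(comparisons), ")")
  }
  votes <- integer(nrow(target_m))
  for (i in seq_along(comparisons)) {
    res <- differential_comparison(target_m, comparisons[[i]],
                                   n_subsample = n_subsample, seed = seed + i)
    marked <- res$logfc >= lfc_min & res$p_adj < alpha & res$logfc > 0
    votes <- votes + as.integer(marked)
  }
  names(votes) <- rownames(target_m) %||% as.character(seq_len(nrow(target_m)))
  structure(
    list(sites = names(votes)[votes > vote_min],
         votes = votes,
         thresholds = list(lfc_min = lfc_min, alpha = alpha,
                           vote_min = vote_min,
                           n_comparisons = length(comparisons))),
    class = "meth_signature"
  )
}

#' @export
print.meth_signature <- function(x, ...) {
  cat("meth_signature:", length(x$sites), "sites selected (votes >",
      x$thresholds$vote_min, "of", x$thresholds$n_comparisons, "comparisons)\n")
  invisible(x)
}

#' Map signature sites to methylation windows
#'
#' Each selected site maps to the 300 bp window containing its genomic
#' position; duplicate windows collapse to one bin. Sites falling outside
#' the genome's full-window grid are an error naming the site.
#'
#' @param signature A [build_signature()] result.
#' @param site_positions Data.frame with `site`, `chrom`, `pos`.
#' @param genome A [genome_model()].
#' @param width Window width (default 300 bp).
#' @return A list with `bins` (unique window ids), `mapping` (site to bin),
#'   and `multiplicity` (sites per bin).
#' @export
map_signature_to_bins <- function(signature, site_positions, genome,
                                  width = 300) {
  sel <- site_positions[site_positions$site %in% signature$sites, , drop = FALSE]
  if (!nrow(sel)) stop_data("no signature sites with positions")
  idx <- genome_chrom_index(genome, sel$chrom)
  n_win <- floor(genome$chroms$length[idx] / width)
  win_i <- floor(sel$pos / width)
  outside <- sel$pos < 0 | win_i >= n_win
  if (any(outside)) {
    stop_data("site(s) outside the genome window grid: ",
              paste(utils::head(sel$site[outside], 10), collapse = ", "))
  }
  bin <- window_id(sel$chrom, win_i * width)
  mult <- table(bin)
  list(bins = unique(bin),
       mapping = data.frame(site = sel$site, bin = bin, stringsAsFactors = FALSE),
       multiplicity = mult)
}
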