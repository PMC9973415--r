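#' Build a healthy reference panel
#'
#' The null model for every z-score: per-feature mean and SD across healthy
#' control samples. Features with SD below `eps` are flagged and excluded
#' from downstream z-scores (a zero-variance null makes the z undefined).
#' The per-sample feature matrix is retained so empirical percentiles of
#' derived scores can be computed.
#'
#' @param samples A list of named numeric vectors (one per healthy sample,
#'   identical feature names) or a features x samples matrix.
#' @param eps SD threshold below which a feature is flagged (default 1e-8).
#' @return An object of class `healthy_panel` with fields `features`,
#'   `mean`, `sd`, `median`, `flagged`, `n_samples`, `values`.
#' @export
build_healthy_panel <- function(samples, eps = 1e-8) {
  if (is.matrix(samples)) {
    mat <- samples
  } else {
    if (length(samples) < 2L) stop_data("need at least 2 healthy samples")
    ref <- names(samples[[1]])
    if (is.null(ref)) stop_data("samples must have named features")
    for (i in seq_along(samples)) {
      diff <- c(setdiff(ref, names(samples[[i]])),
                setdiff(names(samples[[i]]), ref))
      if (length(diff)) {
        stop_data("sample ", i, " feature mismatch: ",
                  paste(utils::head(diff, 10), collapse = ", "))
      }
    }
    mat <- matrix(unlist(lapply(samples, function(s) s[ref])),
                  nrow = length(ref), ncol = length(samples),
                  dimnames = list(ref, names(samples)))
  }
  if (ncol(mat) < 2L) stop_data("need at least 2 healthy samples")
  mu <- rowMeans(mat)
  sd <- apply(mat, 1, stats::sd)
  structure(
    list(features = rownames(mat), mean = mu, sd = sd,
         median = apply(mat, 1, stats::median),
         flagged = sd < eps, n_samples = ncol(mat), values = mat),
    class = "healthy_panel"
  )
}

#' @export
print.healthy_panel <- function(x, ...) {
  cat("healthy_panel:", length(x$features), "features over", x$n_samples,
      "samples;", sum(x$flagged), "flagged (near-zero SD)\n")
  invisible(x)
}

#' Per-feature z-scores against a healthy panel, with aggregates
#'
#' Computes `z = (x - mean) / sd` per unflagged feature and two aggregate
#' conventions: the default signed, variance-normalized sum `sum(z) /
#' sqrt(n)` (unit-variance under the healthy null regardless of feature
#' count) and the mean absolute z as an alternate. Classification against
#' the panel always uses empirical healthy percentiles of the same
#' aggregate, so the convention choice does not move the threshold logic.
#'
#' @param values Named numeric vector of sample feature values.
#' @param panel A [build_healthy_panel()] panel covering those features.
#' @return An object of class `zscore_summary` with fields `z`,
#'   `aggregate`, `mean_abs`, `n_features`.
#' @export
zscore_summary <- function(values, panel) {
  keep <- panel$features[!panel$flagged]
  if (!length(keep)) stop_data("all panel features flagged (zero variance)")
  missing <- setdiff(keep, names(values))
  if (length(missing)) {
    stop_data("sample missing panel features: ",
              paste(utils::head(missing, 10), collapse = ", "))
  }
  z <- (values[keep] - panel$mean[keep]) / panel$sd[keep]
  structure(
    list(z = z,
         aggregate = sum(z) / sqrt(length(z)),
         mean_abs = mean(abs(z)),
         n_features = length(z)),
    class = "zscore_summary"
  )
}

#' @export
print.zscore_summary <- function(x, ...) {
  cat("zscore_summary:", x$n_features, "features; aggregate =",
      signif(x$aggregate, 4), "; mean|z| =", signif(x$mean_abs, 4), "\n")
  invisible(x)
}

#' Classify a score against the healthy 90th percentile
#'
#' The positivity threshold used throughout the longitudinal analyses: the
#' empirical 90th percentile (linear interpolation) of the healthy control
#' scores. A sample is called positive only when its score strictly exceeds
#' the threshold.
#'
#' @param score Numeric score(s) to classify.
#' @param healthy_scores Numeric vector of >= 5 healthy control scores.
#' @param probs Percentile used for the threshold (default 0.9).
#' @return A list with `threshold` and logical `positive`.
#' @export
healthy_threshold_classify <- function(score, healthy_scores, probs = 0.9) {
  if (length(healthy_scores) < 5L) {
    stop_data("need at least 5 healthy scores for a percentile threshold")
  }
  threshold <- unname(stats::quantile(healthy_scores, probs = probs, type = 7))
  list(threshold = threshold, positive = score > threshold)
}
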