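# Orchestration: build healthy panels, reduce one sample to its six
# integration metrics, and run the cohort end-to-end (metrics -> labels ->
# mixed model -> baseline-normalized scores).

#' Assemble a run configuration
#'
#' Collects the inputs and the analysis constants. All thresholds default
#' to the documented values: tumor-fraction positivity > 0.03, >= 0.1X
#' short-fragment coverage, healthy 90th-percentile classification,
#' signature selection at M-scale log fold change >= 2 with BH-adjusted
#' p < 0.05 and votes > 21, 10 requested CV folds.
#'
#' @param genome A [genome_model()].
#' @param records,schedule Clinical cohort tables
#'   (see [make_clinical_fixture()]).
#' @param healthy Named list of healthy-control inputs; each element a list
#'   with `fragments` (a [fragment_set()]) and optionally `medip_windows`.
#' @param samples Named list of patient-timepoint inputs, named
#'   `"<patient_id>.<timepoint>"`, same element structure as `healthy`.
#' @param loci Targeted-ratio loci (BED-like data.frame), e.g. PRC1 sites.
#' @param sites Coverage site centers (data.frame `chrom`, `center`), e.g.
#'   liver open-chromatin sites.
#' @param signature_bins Character vector of methylation window ids.
#' @param thresholds Optional overrides for the defaults above.
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(genome, records, schedule, healthy, samples,
                       loci = NULL, sites = NULL, signature_bins = NULL,
                       thresholds = list(), seed = 1L) {
  defaults <- list(tumor_fraction = 0.03, min_short_coverage = 0.1,
                   healthy_percentile = 0.9, lfc_min = 2, alpha = 0.05,
                   vote_min = 21L, n_folds = 10L)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown)) {
    stop_config("unknown threshold(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(thresholds)] <- thresholds
  structure(
    list(genome = genome, records = records, schedule = schedule,
         healthy = healthy, samples = samples, loci = loci, sites = sites,
         signature_bins = signature_bins, thresholds = defaults, seed = seed),
    class = "run_config"
  )
}

#' Build all healthy panels for a cohort run
#'
#' From the healthy-control fragment sets: per-length size-proportion
#' panel (90-150 bp), 5 Mb and 100 kb ratio panels, central-coverage
#' panel, the copy-number count panel (GC-corrected, depth-normalized)
#' plus the derived log2-ratio panel, and — when methylation windows are
#' supplied — the healthy methylation-score distribution for thresholding.
#'
#' @param config A [run_config()].
#' @return A list of [build_healthy_panel()] panels.
#' @export
build_cohort_panels <- function(config) {
  healthy <- config$healthy
  if (is.null(healthy) || length(healthy) < 2L) {
    stop_config("need at least 2 designated healthy samples")
  }
  genome <- config$genome
  size_feats <- list(); ratio5 <- list(); ratio100 <- list()
  central <- list(); cn_counts <- list()
  for (nm in names(healthy)) {
    frags <- healthy[[nm]]$fragments
    p <- size_proportions(size_distribution(frags))
    size_feats[[nm]] <- p[as.character(90:150)]
    prof <- suppressWarnings(fragment_ratio_profile(frags, genome))
    v5 <- prof$bins5$ratio_scaled; names(v5) <- prof$bins5$bin_id
    ratio5[[nm]] <- v5[!is.na(v5)]
    v1 <- prof$bins100$ratio_scaled; names(v1) <- prof$bins100$bin_id
    ratio100[[nm]] <- v1[!is.na(v1)]
    if (!is.null(config$sites)) {
      central[[nm]] <- c(central = site_coverage(frags, config$sites)$central)
    }
    bc <- bin_fragment_counts(frags, genome, 1e6,
                              length_classes = list(all = c(0, Inf)))
    bins <- bc$bins[!bc$bins$excluded, , drop = FALSE]
    names(bins)[names(bins) == "all"] <- "count"
    bins <- suppressWarnings(gc_correct_counts(bins))
    v <- normalize_depth(bins$count_corr)
    names(v) <- window_id(bins$chrom, bins$start)
    cn_counts[[nm]] <- v
  }
  panels <- list(
    size = build_healthy_panel(size_feats),
    ratio5 = build_healthy_panel(common_features(ratio5)),
    ratio100 = build_healthy_panel(common_features(ratio100)),
    cn_counts = build_healthy_panel(cn_counts)
  )
  if (length(central)) panels$central <- build_healthy_panel(central)
  # log2-ratio panel: every healthy sample against the count-panel median
  ratios <- lapply(names(healthy), function(nm) {
    v <- cn_counts[[nm]]
    med <- panels$cn_counts$median[names(v)]
    ok <- v > 0 & med > 0
    r <- rep(NA_real_, length(v)); names(r) <- names(v)
    r[ok] <- log2(v[ok] / med[ok])
    r[!is.na(r)]
  })
  names(ratios) <- names(healthy)
  panels$cn_ratio <- build_healthy_panel(common_features(ratios))
  panels
}

# Restrict a list of named vectors to the features present in all of them.
common_features <- function(vectors) {
  feats <- Reduce(intersect, lapply(vectors, names))
  if (!length(feats)) stop_data("healthy samples share no features")
  lapply(vectors, function(v) v[feats])
}

#' Reduce one sample to its six integration metrics
#'
#' Runs the fragmentomic, copy-number, and methylation analyses for a
#' single sample against the cohort's healthy panels and returns one row:
#' `cn_z` (arm-weighted chromosome 3/6/8 score), `size_z` (90-150 bp
#' size aggregate), `ratio_z` (genome-wide 5 Mb ratio aggregate), `prc1_z`
#' (targeted-locus aggregate), `liver_coverage_z` (central-coverage z at
#' the supplied sites), and `um_methylation_score` (posterior sum over
#' signature bins; `NA` when no methylation input or signature is
#' supplied).
#'
#' @param config A [run_config()].
#' @param sample_id Name of an element of `config$samples`.
#' @param panels A [build_cohort_panels()] result.
#' @return A one-row data.frame.
#' @export
run_sample <- function(config, sample_id, panels) {
  input <- config$samples[[sample_id]]
  if (is.null(input)) stop_config("unknown sample: ", sample_id)
  frags <- input$fragments
  if (is.null(frags)) stop_config("sample ", sample_id, " has no fragments")
  genome <- config$genome

  size_z <- size_zscore(size_distribution(frags), panels$size)$aggregate
  prof <- suppressWarnings(fragment_ratio_profile(frags, genome))
  ratio_z <- profile_zscore(prof, panels$ratio5)$aggregate
  prc1_z <- if (!is.null(config$loci)) {
    targeted_profile_zscore(prof, config$loci, panels$ratio100)$aggregate
  } else NA_real_
  liver_z <- if (!is.null(config$sites) && !is.null(panels$central)) {
    central_coverage_zscore(site_coverage(frags, config$sites), panels$central)
  } else NA_real_

  bc <- bin_fragment_counts(frags, genome, 1e6,
                            length_classes = list(all = c(0, Inf)))
  bins <- bc$bins[!bc$bins$excluded, , drop = FALSE]
  names(bins)[names(bins) == "all"] <- "count"
  bins <- suppressWarnings(gc_correct_counts(bins))
  ratio <- copy_ratio(bins, panels$cn_counts)
  cn <- cn_zscore(ratio, panels$cn_ratio)

  meth <- NA_real_
  if (!is.null(input$medip_windows) && !is.null(config$signature_bins)) {
    bg <- fit_nonmethylated(input$medip_windows)
    fit <- em_fit(input$medip_windows, bg)
    meth <- methylation_score(fit, config$signature_bins)
  }
  data.frame(
    sample_id = sample_id,
    cn_z = cn$weighted_score,
    size_z = size_z,
    ratio_z = ratio_z,
    prc1_z = prc1_z,
    liver_coverage_z = liver_z,
    um_methylation_score = meth,
    stringsAsFactors = FALSE
  )
}

#' Run the cohort end-to-end
#'
#' Builds the healthy panels, reduces every sample to its metric row,
#' labels timepoints from the clinical table, scales the metrics, fits the
#' mixed-effect integration model with patient-grouped CV, and
#' baseline-normalizes the integrated probabilities. Metrics that are
#' entirely `NA` (e.g. no methylation inputs) are dropped from the model.
#'
#' @param config A [run_config()].
#' @return A list with `panels`, `metrics`, `labels`, `fit`, `scores`, and
#'   `summary` (the [cohort_summary()] numbers).
#' @export
run_cohort <- function(config) {
  panels <- build_cohort_panels(config)
  rows <- lapply(names(config$samples), function(nm) run_sample(config, nm, panels))
  metrics <- do.call(rbind, rows)
  ids <- strsplit(metrics$sample_id, ".", fixed = TRUE)
  metrics$patient_id <- vapply(ids, `[`, character(1), 1)
  metrics$timepoint <- vapply(ids, `[`, character(1), 2)
  metric_cols <- setdiff(names(metrics), c("sample_id", "patient_id", "timepoint"))
  metric_cols <- metric_cols[colSums(is.na(metrics[metric_cols])) == 0]
  labels <- label_timepoints(config$records, config$schedule)
  scaled <- scale_metrics(metrics[, c("patient_id", "timepoint", metric_cols)],
                          metric_cols)
  fit <- fit_integration_model(scaled, labels,
                               n_folds = config$thresholds$n_folds,
                               seed = config$seed)
  scores <- normalize_to_baseline(fit)
  list(panels = panels, metrics = metrics, labels = labels, fit = fit,
       scores = scores,
       summary = cohort_summary(config$records, config$schedule))
}
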