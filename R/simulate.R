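# Synthetic-data generators. Each generator is seeded, returns its ground
# truth alongside the data, and has closed-form moments so recovery tests
# can check it against independent oracles.

#' Fragment length model
#'
#' Gaussian mixture over fragment lengths. The default emulates a healthy
#' plasma spectrum: a dominant mono-nucleosome mode at 167 bp plus a minor
#' sub-nucleosomal short-fragment mode; tumor-shifted samples raise the
#' short-mode weight.
#'
#' @param components Data.frame with columns `mean`, `sd`, `weight`
#'   (weights sum to 1; means in 50-400 bp).
#' @param n_fragments Number of fragments to draw.
#' @return An object of class `fragment_length_model`.
#' @export
fragment_length_model <- function(components = data.frame(
                                    mean = c(120, 167),
                                    sd = c(15, 12),
                                    weight = c(0.08, 0.92)),
                                  n_fragments = 1e5) {
  stopifnot(all(c("mean", "sd", "weight") %in% names(components)))
  if (abs(sum(components$weight) - 1) > 1e-8) {
    stop_config("component weights must sum to 1")
  }
  if (any(components$mean < 50 | components$mean > 400)) {
    stop_config("component means must lie in [50, 400] bp")
  }
  if (any(components$sd < 0)) stop_config("component SDs must be >= 0")
  if (n_fragments <= 0) stop_config("n_fragments must be positive")
  structure(list(components = components, n_fragments = n_fragments),
            class = "fragment_length_model")
}

#' Mixture CDF of a fragment length model
#'
#' Closed-form P(length <= x) for the Gaussian mixture, used as the
#' independent oracle for simulated length distributions. Zero-SD
#' components contribute a step at their mean.
#'
#' @param model A [fragment_length_model()].
#' @param x Lengths in bp.
#' @return Numeric vector of probabilities.
#' @export
fragment_length_cdf <- function(model, x) {
  comp <- model$components
  sapply(x, function(q) {
    sum(ifelse(comp$sd > 0,
               comp$weight * stats::pnorm(q, comp$mean, comp$sd),
               comp$weight * as.numeric(q >= comp$mean)))
  })
}

#' Simulate a fragment set
#'
#' Draws fragment lengths from the Gaussian mixture (rounded, clipped to
#' >= 20 bp) and places each fragment uniformly on the genome (chromosome
#' chosen proportional to length, start uniform over valid positions).
#' Bit-for-bit reproducible under a fixed seed.
#'
#' @param model A [fragment_length_model()].
#' @param genome A [genome_model()].
#' @param seed Integer RNG seed.
#' @return A [fragment_set()].
#' @export
simulate_fragments <- function(model, genome, seed = 1L) {
  if (nrow(genome$chroms) == 0L) stop_config("empty genome")
  n <- model$n_fragments
  comp <- model$components
  withr_seed(seed, {
    k <- sample.int(nrow(comp), n, replace = TRUE, prob = comp$weight)
    len <- pmax(20, round(stats::rnorm(n, comp$mean[k], comp$sd[k])))
    ci <- sample.int(nrow(genome$chroms), n, replace = TRUE,
                     prob = genome$chroms$length)
    max_start <- pmax(0, genome$chroms$length[ci] - len)
    start <- floor(stats::runif(n) * (max_start + 1))
    fragment_set(genome$chroms$chrom[ci], start, start + len, genome)
  })
}

# Evaluate expr with a local, restored RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate binned counts with copy-number events
#'
#' Per-bin counts are Poisson with mean `depth * (1 + tumor_fraction *
#' (multiplier - 1))` inside each CNV segment and `depth` elsewhere — the
#' expected dilution of a clonal copy-number event by the non-tumor cfDNA
#' background.
#'
#' @param genome A [genome_model()].
#' @param segments Data.frame with columns `chrom`, `start`, `end`,
#'   `multiplier` (copy state relative to diploid; 0.5 = monosomy, 1.5 =
#'   single-copy gain), `tumor_fraction`. Segments on one chromosome must
#'   not overlap.
#' @param depth Expected count per bin in a diploid background.
#' @param seed Integer RNG seed.
#' @param width Bin width in bp (default 1 Mb).
#' @return A data.frame of bins with `count` and `expected` columns.
#' @export
simulate_cnv_counts <- function(genome, segments = NULL, depth = 1000,
                                seed = 1L, width = 1e6) {
  bins <- build_windows(genome, width)
  bins$expected <- rep(as.numeric(depth), nrow(bins))
  if (!is.null(segments) && nrow(segments) > 0L) {
    stopifnot(all(c("chrom", "start", "end", "multiplier", "tumor_fraction")
                  %in% names(segments)))
    if (any(segments$end <= segments$start)) stop_data("segment end <= start")
    if (any(segments$multiplier <= 0)) stop_data("multiplier must be > 0")
    if (any(segments$tumor_fraction < 0 | segments$tumor_fraction > 1)) {
      stop_data("tumor_fraction must lie in [0, 1]")
    }
    for (ch in unique(segments$chrom)) {
      s <- segments[segments$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1L && any(s$start[-1] < s$end[-nrow(s)])) {
        stop_data("overlapping segments on ", ch)
      }
    }
    mid <- (bins$start + bins$end) / 2
    for (i in seq_len(nrow(segments))) {
      hit <- bins$chrom == segments$chrom[i] &
        mid >= segments$start[i] & mid < segments$end[i]
      bins$expected[hit] <- depth *
        (1 + segments$tumor_fraction[i] * (segments$multiplier[i] - 1))
    }
  }
  withr_seed(seed, bins$count <- stats::rpois(nrow(bins), bins$expected))
  bins
}

#' Ground-truth parameters for the cfMeDIP generative mixture
#'
#' Holds the generative parameters of the two-component negative-binomial
#' model: mixing weight `pi` (probability a CpG-bearing window is
#' methylated), unmethylated log-mean coefficients `beta0 + beta1 * gc`,
#' methylated log-mean coefficients `gamma0 + gamma1 * cpg`, and the two
#' dispersions (NB variance `mu + mu^2 / phi`).
#'
#' @param pi Mixing weight in (0, 1) (0 and 1 allowed for degenerate
#'   simulations).
#' @param beta0,beta1 Unmethylated-component coefficients (log link, GC
#'   covariate).
#' @param gamma0,gamma1 Methylated-component coefficients (log link, CpG
#'   covariate).
#' @param phi0,phi1 Dispersions, both > 0.
#' @return An object of class `methylation_truth`.
#' @export
methylation_truth <- function(pi = 0.3, beta0 = 2, beta1 = 1.5,
                              gamma0 = 3, gamma1 = 0.08,
                              phi0 = 5, phi1 = 8) {
  if (pi < 0 || pi > 1) stop_config("pi must lie in [0, 1]")
  if (phi0 <= 0 || phi1 <= 0) stop_config("dispersions must be > 0")
  structure(list(pi = pi, beta0 = beta0, beta1 = beta1,
                 gamma0 = gamma0, gamma1 = gamma1,
                 phi0 = phi0, phi1 = phi1),
            class = "methylation_truth")
}

#' Simulate cfMeDIP window counts from the generative mixture
#'
#' Windows with at least one CpG are latently methylated with probability
#' `pi`; zero-CpG windows are deterministically unmethylated (the model's
#' identifiability assumption — immunoprecipitation cannot enrich a window
#' with nothing to methylate). Counts are negative binomial with log-mean
#' `beta0 + beta1 * gc` (unmethylated) or `gamma0 + gamma1 * cpg`
#' (methylated).
#'
#' @param genome A [genome_model()].
#' @param truth A [methylation_truth()].
#' @param seed Integer RNG seed.
#' @param windows Optional pre-built 300 bp window table (from
#'   [build_windows()]); built from the genome when omitted.
#' @return A list with `windows` (with a `count` column) and `latent`
#'   (logical methylation state per window).
#' @export
simulate_medip_windows <- function(genome, truth, seed = 1L, windows = NULL) {
  if (!inherits(truth, "methylation_truth")) {
    stop_config("truth must be a methylation_truth object")
  }
  if (is.null(windows)) windows <- build_windows(genome, 300)
  withr_seed(seed, {
    n <- nrow(windows)
    latent <- rep(FALSE, n)
    has_cpg <- windows$cpg > 0
    latent[has_cpg] <- stats::runif(sum(has_cpg)) < truth$pi
    mu <- ifelse(latent,
                 exp(truth$gamma0 + truth$gamma1 * windows$cpg),
                 exp(truth$beta0 + truth$beta1 * windows$gc))
    windows$count <- stats::rnbinom(n, size = ifelse(latent, truth$phi1, truth$phi0),
                                    mu = mu)
    list(windows = windows, latent = latent)
  })
}

#' Simulate cohort-labelled methylation array matrices
#'
#' Background beta values share a common per-site distribution across all
#' cohorts (site-level M means drawn once, within-cohort noise on the
#' M-value scale); planted sites are shifted upward by `effect_size`
#' M-units in the designated target cohort only, then back-transformed so
#' all betas lie strictly in (0, 1).
#'
#' @param n_cohorts Number of cohorts (target cohort is cohort 1).
#' @param n_samples_per_cohort Samples per cohort (>= 2).
#' @param n_sites Number of array sites.
#' @param planted Integer indices of sites hypermethylated in the target
#'   cohort.
#' @param effect_size Shift on the M-value scale.
#' @param seed Integer RNG seed.
#' @param site_sd Within-cohort M-value SD (default 1).
#' @return A list with `beta` (sites x samples matrix), `labels` (cohort of
#'   each sample), `sites` (data.frame with `site`, `chrom`, `pos`),
#'   `planted`.
#' @export
simulate_methylation_arrays <- function(n_cohorts, n_samples_per_cohort,
                                        n_sites, planted = integer(0),
                                        effect_size = 4, seed = 1L,
                                        site_sd = 1) {
  if (n_samples_per_cohort < 2L) {
    stop_config("need >= 2 samples per cohort (variance undefined otherwise)")
  }
  if (length(planted) && any(planted < 1 | planted > n_sites)) {
    stop_config("planted sites must index into 1..n_sites")
  }
  withr_seed(seed, {
    mu_site <- stats::rnorm(n_sites, mean = -1, sd = 2)
    n_total <- n_cohorts * n_samples_per_cohort
    labels <- rep(paste0("cohort", seq_len(n_cohorts)),
                  each = n_samples_per_cohort)
    m <- matrix(stats::rnorm(n_sites * n_total, mean = mu_site, sd = site_sd),
                nrow = n_sites, ncol = n_total)
    if (length(planted)) {
      target_cols <- which(labels == "cohort1")
      m[planted, target_cols] <- m[planted, target_cols] + effect_size
    }
    # strictly in (0,1): plogis cannot reach the endpoints for the M range
    # this generator produces (|M| well below 1000)
    beta <- stats::plogis(m * log(2))
    rownames(beta) <- paste0("cg", sprintf("%06d", seq_len(n_sites)))
    sites <- data.frame(site = rownames(beta),
                        chrom = "chr1",
                        pos = seq_len(n_sites) * 1000,
                        stringsAsFactors = FALSE)
    list(beta = beta, labels = labels, sites = sites, planted = planted)
  })
}

#' Simulate longitudinal metric trajectories with relapse labels
#'
#' Emulates the per-sample, per-timepoint metric matrix of a monitoring
#' cohort. The latent ctDNA signal is 1 at baseline (tumor in place),
#' drops to 0 after treatment for non-relapsers, and for relapsers regrows
#' quadratically toward the relapse date (`(t / relapse_months)^2`, capped
#' at 1 at and after relapse). Each metric is `baseline + slope * signal +
#' patient intercept + noise`.
#'
#' @param cohort A list with `records` and `schedule`
#'   (see [make_clinical_fixture()]).
#' @param params Data.frame with one row per metric: `metric`, `baseline`,
#'   `slope`, `noise_sd`. Default: the six integration metrics with
#'   baseline 0, slope 3, noise SD 0.5.
#' @param seed Integer RNG seed.
#' @param intercept_sd SD of the per-patient random intercept (default 0.3).
#' @return A list with `metrics` (rows = collected patient-timepoints),
#'   `labels` (from [label_timepoints()]), and `truth` (latent signal and
#'   intercepts).
#' @export
simulate_metric_timeseries <- function(cohort,
                                       params = default_trajectory_params(),
                                       seed = 1L, intercept_sd = 0.3) {
  records <- cohort$records
  schedule <- cohort$schedule
  stopifnot(all(c("metric", "baseline", "slope", "noise_sd") %in% names(params)))
  collected <- schedule[schedule$collected == "yes", , drop = FALSE]
  tp <- timepoint_months()
  month <- tp[collected$timepoint]
  rec <- records[match(collected$patient_id, records$patient_id), , drop = FALSE]
  signal <- ifelse(month == 0, 1, 0)
  rel <- rec$relapse == "yes"
  post <- rel & month > 0
  signal[post] <- pmin(1, (month[post] / rec$relapse_months[post])^2)
  withr_seed(seed, {
    b <- stats::rnorm(nrow(records), 0, intercept_sd)
    names(b) <- records$patient_id
    metrics <- data.frame(patient_id = collected$patient_id,
                          timepoint = collected$timepoint,
                          stringsAsFactors = FALSE)
    for (j in seq_len(nrow(params))) {
      metrics[[params$metric[j]]] <- params$baseline[j] +
        params$slope[j] * signal +
        b[collected$patient_id] +
        stats::rnorm(nrow(collected), 0, params$noise_sd[j])
    }
    labels <- label_timepoints(records, schedule)
    list(metrics = metrics, labels = labels,
         truth = list(signal = signal, intercepts = b))
  })
}

#' @rdname simulate_metric_timeseries
#' @export
default_trajectory_params <- function() {
  data.frame(
    metric = c("cn_z", "size_z", "ratio_z", "prc1_z",
               "liver_coverage_z", "um_methylation_score"),
    baseline = 0,
    slope = 3,
    noise_sd = 0.5,
    stringsAsFactors = FALSE
  )
}
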