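# cfMeDIP-seq methylation caller: a two-component negative-binomial
# mixture over 300 bp window counts. The unmethylated component is an NB
# regression on GC fit from zero-CpG windows and held fixed; the
# methylated component (NB regression on CpG count) and the mixing weight
# are estimated by EM; every window receives a posterior probability of
# being methylated.

# NB log-density in mean/dispersion form (variance mu + mu^2/phi);
# phi = Inf degenerates to Poisson.
dnb_log <- function(x, mu, phi) {
  if (length(phi) == 1L && is.infinite(phi)) {
    stats::dpois(x, lambda = mu, log = TRUE)
  } else {
    stats::dnbinom(x, size = phi, mu = mu, log = TRUE)
  }
}

#' Count fragments in methylation windows
#'
#' Assigns each fragment to the 300 bp window containing its midpoint and
#' returns the window table with counts; blacklisted windows are excluded
#' (their fragments tallied separately).
#'
#' @param frag A [fragment_set()].
#' @param genome A [genome_model()].
#' @param width Window width (default 300 bp).
#' @return A list with `windows` (including `count`) and `excluded_fragments`.
#' @export
count_windows <- function(frag, genome, width = 300) {
  bc <- bin_fragment_counts(frag, genome, width,
                            length_classes = list(all = c(0, Inf)))
  win <- bc$bins
  names(win)[names(win) == "all"] <- "count"
  win$cpg <- genome_cpg_at(genome, win$chrom, (win$start + win$end) / 2, width)
  excluded <- sum(win$count[win$excluded]) + bc$unbinned
  win <- win[!win$excluded, , drop = FALSE]
  rownames(win) <- NULL
  list(windows = win, excluded_fragments = excluded)
}

#' Fit the fixed unmethylated component
#'
#' Negative-binomial regression `log mu0 = beta0 + beta1 * gc` over
#' zero-CpG windows (which cannot be methylated, so they identify the
#' background enrichment as a function of GC alone). Dispersion is
#' estimated by maximum likelihood; near-Poisson counts (diverging
#' dispersion) fall back to a Poisson fit with a warning. The fitted model
#' is frozen before EM.
#'
#' @param windows Window table with `count`, `cpg`, `gc`.
#' @param min_windows Minimum zero-CpG windows required (default 100).
#' @return An object of class `nonmethylated_model` with `beta0`, `beta1`,
#'   `phi0` (`Inf` for the Poisson fallback), `deviance`, `n`.
#' @export
fit_nonmethylated <- function(windows, min_windows = 100L) {
  zw <- windows[windows$cpg == 0, , drop = FALSE]
  if (nrow(zw) == 0L) stop_data("no zero-CpG windows: unmethylated model unidentifiable")
  if (nrow(zw) < min_windows) {
    stop_data("need at least ", min_windows, " zero-CpG windows, have ", nrow(zw))
  }
  if (all(zw$count == 0)) stop_data("all zero-CpG window counts are zero")
  if (stats::var(zw$count) == 0) stop_data("zero-CpG counts have no variation")
  fit <- withCallingHandlers(
    tryCatch(MASS::glm.nb(count ~ gc, data = zw),
             error = function(e) NULL),
    warning = function(w) invokeRestart("muffleWarning")
  )
  pois <- stats::glm(count ~ gc, data = zw, family = stats::poisson())
  # near-Poisson counts (no real overdispersion): the NB dispersion is not
  # identified, so fall back to the Poisson background. Decided by the
  # boundary likelihood-ratio between the NB and Poisson fits.
  lr <- if (is.null(fit)) 0 else {
    2 * (as.numeric(stats::logLik(fit)) - as.numeric(stats::logLik(pois)))
  }
  poisson_fallback <- is.null(fit) || lr < stats::qchisq(0.95, df = 1)
  if (poisson_fallback) {
    warning("zero-CpG counts are near-Poisson; falling back to Poisson background")
    fit <- pois
    phi0 <- Inf
  } else {
    phi0 <- fit$theta
  }
  structure(
    list(beta0 = unname(stats::coef(fit)[1]),
         beta1 = unname(stats::coef(fit)[2]),
         phi0 = phi0,
         deviance = stats::deviance(fit),
         n = nrow(zw),
         poisson_fallback = poisson_fallback),
    class = "nonmethylated_model"
  )
}

# Weighted NB regression log mu = g0 + g1 * x maximised by BFGS with
# analytic gradients, warm started so the objective can only improve on
# the starting point (which keeps the EM observed-data log-likelihood
# monotone even when the M-step is run for a bounded number of steps).
fit_weighted_nb <- function(y, x, w, start) {
  nll <- function(par) {
    mu <- exp(pmin(par[1] + par[2] * x, 50))
    phi <- exp(pmin(pmax(par[3], -20), 20))
    -sum(w * stats::dnbinom(y, size = phi, mu = mu, log = TRUE))
  }
  grad <- function(par) {
    mu <- exp(pmin(par[1] + par[2] * x, 50))
    phi <- exp(pmin(pmax(par[3], -20), 20))
    dmu <- w * (y / mu - (y + phi) / (mu + phi))        # d loglik / d mu
    dphi <- w * (digamma(y + phi) - digamma(phi) + log(phi) + 1 -
                   log(mu + phi) - (y + phi) / (mu + phi))
    -c(sum(dmu * mu), sum(dmu * mu * x), sum(dphi * phi))
  }
  # a bounded partial M-step: with the warm start this is a generalized EM
  # update, cheaper per iteration with the same monotonicity guarantee
  opt <- stats::optim(start, nll, gr = grad, method = "BFGS",
                      control = list(maxit = 15, reltol = 1e-9))
  best <- if (opt$value <= nll(start)) opt$par else start
  list(gamma0 = best[1], gamma1 = best[2], phi = exp(best[3]))
}

#' EM fit of the two-component methylation mixture
#'
#' E-step: posterior `r_i = pi f1 / (pi f1 + (1 - pi) f0)` for every
#' CpG-bearing window, with `f0` the frozen unmethylated density and `f1`
#' the methylated NB with log-mean `gamma0 + gamma1 * cpg`. M-step: `pi =
#' mean(r)` and a weighted NB regression update of `(gamma, phi1)` warm
#' started at the previous values. Iterates until the observed-data
#' log-likelihood changes by less than `tol` or `max_iter` is reached; the
#' log-likelihood trace is non-decreasing by construction. Zero-CpG windows
#' enter the likelihood only through the fixed component and receive
#' posterior 0.
#'
#' @param windows Window table with `count`, `cpg`, `gc`.
#' @param fixed A [fit_nonmethylated()] model.
#' @param init Optional list with `pi`, `gamma0`, `gamma1`, `phi1`.
#'   Default: `pi = 0.2`, methylated coefficients from an NB fit to the
#'   top count quartile of CpG-bearing windows.
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter Maximum EM iterations (default 200).
#' @return An object of class `mixture_fit`: `pi`, `gamma0`, `gamma1`,
#'   `phi1`, `posterior` (one per window, 0 for zero-CpG windows),
#'   `loglik_trace`, `converged`, `iterations`, `degenerate_pi`.
#' @export
em_fit <- function(windows, fixed, init = NULL, tol = 1e-6, max_iter = 200L) {
  has_cpg <- windows$cpg > 0
  if (!any(has_cpg)) stop_data("no CpG-bearing windows to fit")
  y <- windows$count[has_cpg]
  cpg <- windows$cpg[has_cpg]
  gc <- windows$gc[has_cpg]
  logf0 <- dnb_log(y, exp(fixed$beta0 + fixed$beta1 * gc), fixed$phi0)
  logf0_zero <- {
    y0 <- windows$count[!has_cpg]
    gc0 <- windows$gc[!has_cpg]
    sum(dnb_log(y0, exp(fixed$beta0 + fixed$beta1 * gc0), fixed$phi0))
  }

  if (is.null(init)) {
    top <- y >= stats::quantile(y, 0.75)
    start_fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y[top] ~ cpg[top])),
      error = function(e) NULL
    )
    init <- if (!is.null(start_fit)) {
      list(pi = 0.2,
           gamma0 = unname(stats::coef(start_fit)[1]),
           gamma1 = unname(stats::coef(start_fit)[2]),
           phi1 = min(start_fit$theta, 1e3))
    } else {
      list(pi = 0.2, gamma0 = log(mean(y[top]) + 1), gamma1 = 0.05, phi1 = 5)
    }
  }
  pi_hat <- init$pi
  par <- c(init$gamma0, init$gamma1, log(init$phi1))

  loglik <- function(pi_hat, par) {
    mu1 <- exp(pmin(par[1] + par[2] * cpg, 50))
    logf1 <- stats::dnbinom(y, size = exp(par[3]), mu = mu1, log = TRUE)
    sum(logsumexp2(log(pi_hat) + logf1, log(1 - pi_hat) + logf0)) + logf0_zero
  }

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  r <- NULL
  for (it in seq_len(max_iter)) {
    # E-step
    mu1 <- exp(pmin(par[1] + par[2] * cpg, 50))
    logf1 <- stats::dnbinom(y, size = exp(par[3]), mu = mu1, log = TRUE)
    lp1 <- log(pi_hat) + logf1
    lp0 <- log(1 - pi_hat) + logf0
    r <- 1 / (1 + exp(lp0 - lp1))
    r[pi_hat <= 0] <- 0
    r[pi_hat >= 1] <- 1
    # M-step
    pi_hat <- min(max(mean(r), 1e-8), 1 - 1e-8)
    w <- pmax(r, 1e-12)
    upd <- fit_weighted_nb(y, cpg, w, par)
    par <- c(upd$gamma0, upd$gamma1, log(upd$phi))
    ll <- loglik(pi_hat, par)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # final E-step so reported posteriors correspond to the returned parameters
  mu1 <- exp(pmin(par[1] + par[2] * cpg, 50))
  logf1 <- stats::dnbinom(y, size = exp(par[3]), mu = mu1, log = TRUE)
  r <- 1 / (1 + exp(log(1 - pi_hat) + logf0 - log(pi_hat) - logf1))
  posterior <- numeric(nrow(windows))
  posterior[has_cpg] <- r
  structure(
    list(pi = pi_hat, gamma0 = par[1], gamma1 = par[2], phi1 = exp(par[3]),
         posterior = posterior,
         window_id = window_id(windows$chrom, windows$start),
         loglik_trace = trace,
         converged = converged,
         iterations = length(trace),
         degenerate_pi = pi_hat <= 1e-6 || pi_hat >= 1 - 1e-6),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("mixture_fit: pi =", signif(x$pi, 4),
      "; gamma = (", signif(x$gamma0, 4), ",", signif(x$gamma1, 4), ")",
      "; phi1 =", signif(x$phi1, 4),
      "; iterations =", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' Methylation score over signature bins
#'
#' The per-sample tumor-methylation burden: the sum of posterior
#' methylation probabilities over the signature bins (range 0 to the
#' number of bins).
#'
#' @param fit A [em_fit()] result.
#' @param signature_bins Character vector of window ids (`"chrom:start"`).
#' @return A single score.
#' @export
methylation_score <- function(fit, signature_bins) {
  idx <- match(signature_bins, fit$window_id)
  if (anyNA(idx)) {
    stop_data("signature bins missing from the fit: ",
              paste(utils::head(signature_bins[is.na(idx)], 10), collapse = ", "))
  }
  sum(fit$posterior[idx])
}

#' Spike-in enrichment QC
#'
#' Fraction of methylated spike-in reads out of all spike-in reads; near 1
#' indicates efficient immunoprecipitation of methylated DNA.
#'
#' @param methylated_count,unmethylated_count Read counts.
#' @return A fraction in `[0, 1]`.
#' @export
qc_spikein <- function(methylated_count, unmethylated_count) {
  total <- methylated_count + unmethylated_count
  if (total <= 0) stop_data("no spike-in reads")
  methylated_count / total
}

#' relH / GoGe CpG enrichment scores
#'
#' From base composition (`n_c`, `n_g`, `n_cg` dinucleotides, total length
#' `len`) of the covered regions and of the genome: `relH = 100 * n_cg /
#' len`, `GoGe = (n_cg * len) / (n_c * n_g)`; the enrichment score for each
#' is the sample value over the genome value. Scores well above 1 indicate
#' successful CpG enrichment.
#'
#' @param sample_stats,genome_stats Lists with `n_c`, `n_g`, `n_cg`, `len`.
#' @return A list with `relH` and `GoGe` enrichment scores (plus the raw
#'   sample/genome values).
#' @export
qc_enrichment <- function(sample_stats, genome_stats) {
  one <- function(s) {
    if (s$n_c * s$n_g == 0) stop_data("zero C or G count")
    list(relH = 100 * s$n_cg / s$len,
         goge = (s$n_cg * s$len) / (s$n_c * s$n_g))
  }
  smp <- one(sample_stats)
  gen <- one(genome_stats)
  list(relH = smp$relH / gen$relH,
       GoGe = smp$goge / gen$goge,
       sample = smp, genome = gen)
}
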