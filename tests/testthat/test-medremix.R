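# Simulated windows shared across the caller's tests (20k windows, the
# generative parameters the recovery checks assert against).
medremix_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- medip_genome(20000)
      truth <- methylation_truth(pi = 0.3, beta0 = 2, beta1 = 1.5,
                                 gamma0 = 3, gamma1 = 0.08, phi0 = 5, phi1 = 8)
      sim <- simulate_medip_windows(g, truth, seed = 7)
      bg <- fit_nonmethylated(sim$windows)
      fit <- em_fit(sim$windows, bg)
      cache <<- list(genome = g, truth = truth, sim = sim, bg = bg, fit = fit)
    }
    cache
  }
})

test_that("window counting assigns midpoints and conserves fragments", {
  g <- genome_model("chr1", 3000)
  frag <- fragment_set("chr1", 100, 267, g)  # midpoint 183 -> window 1
  cw <- count_windows(frag, g)
  expect_equal(cw$windows$count[1], 1L)
  expect_equal(sum(cw$windows$count), 1L)
  frag2 <- simulate_fragments(healthy_length_model(n = 5000),
                              genome_model("chr1", 1e6), seed = 2)
  cw2 <- count_windows(frag2, genome_model("chr1", 1e6))
  expect_equal(sum(cw2$windows$count) + cw2$excluded_fragments, 5000L)
})

test_that("zero-CpG NB regression recovers the background parameters", {
  case <- medremix_case()
  bg <- case$bg
  expect_lt(abs(bg$beta0 - 2), 0.1)
  expect_lt(abs(bg$beta1 - 1.5), 0.1)
  expect_lt(abs(bg$phi0 / 5 - 1), 0.2)
  expect_false(bg$poisson_fallback)
  # null slope recovery
  g <- medip_genome(10000)
  truth0 <- methylation_truth(pi = 0, beta0 = 2, beta1 = 0, phi0 = 5)
  sim0 <- simulate_medip_windows(g, truth0, seed = 11)
  bg0 <- fit_nonmethylated(sim0$windows)
  expect_lt(abs(bg0$beta1), 0.05)
  # Poisson-generated counts: flagged fallback, not an error
  simp <- sim0
  simp$windows$count <- withr::with_seed(1, rpois(nrow(simp$windows),
    exp(2 + 1.5 * simp$windows$gc)))
  expect_warning(bgp <- fit_nonmethylated(simp$windows), "Poisson")
  expect_true(bgp$poisson_fallback)
  expect_true(is.infinite(bgp$phi0))
  # unidentifiable without zero-CpG windows
  nz <- sim0$windows[sim0$windows$cpg > 0, ]
  expect_error(fit_nonmethylated(nz), "zero-CpG")
})

test_that("EM recovers the mixture parameters with a monotone likelihood", {
  case <- medremix_case()
  fit <- case$fit
  expect_true(fit$converged)
  expect_lt(abs(fit$pi - 0.3), 0.05)
  expect_lt(abs(fit$gamma0 / 3 - 1), 0.15)
  expect_lt(abs(fit$gamma1 / 0.08 - 1), 0.15)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  # zero-CpG windows carry posterior 0 by construction
  expect_true(all(fit$posterior[case$sim$windows$cpg == 0] == 0))
})

test_that("posteriors agree with a brute-force two-density oracle", {
  case <- medremix_case()
  w <- case$sim$windows
  fit <- case$fit; bg <- case$bg
  idx <- which(w$cpg > 0)[1:200]
  f0 <- dnbinom(w$count[idx], size = bg$phi0, mu = exp(bg$beta0 + bg$beta1 * w$gc[idx]))
  f1 <- dnbinom(w$count[idx], size = fit$phi1,
                mu = exp(fit$gamma0 + fit$gamma1 * w$cpg[idx]))
  oracle <- fit$pi * f1 / (fit$pi * f1 + (1 - fit$pi) * f0)
  expect_lt(max(abs(oracle - fit$posterior[idx])), 1e-6)
})

test_that("EM output is invariant to window order and handles the null", {
  case <- medremix_case()
  w <- case$sim$windows
  perm <- withr::with_seed(3, sample(nrow(w)))
  fit_perm <- em_fit(w[perm, ], case$bg)
  expect_lt(abs(fit_perm$pi - case$fit$pi), 1e-6)
  expect_lt(max(abs(fit_perm$posterior - case$fit$posterior[perm])), 1e-6)
  # all-unmethylated data: pi collapses toward 0
  g <- medip_genome(10000)
  sim0 <- simulate_medip_windows(g, methylation_truth(pi = 0), seed = 13)
  bg0 <- fit_nonmethylated(sim0$windows)
  fit0 <- em_fit(sim0$windows, bg0)
  expect_lt(fit0$pi, 0.05)
  expect_lt(mean(fit0$posterior[sim0$windows$cpg > 0]), 0.05)
})

test_that("a high-count CpG-rich window gets posterior near 1", {
  case <- medremix_case()
  w <- case$sim$windows
  j <- which(w$cpg > 0)[1]
  w$cpg[j] <- 40
  w$count[j] <- round(10 * exp(case$bg$beta0 + case$bg$beta1 * w$gc[j]))
  fit <- em_fit(w, case$bg)
  expect_gt(fit$posterior[j], 0.99)
})

test_that("methylation score sums posteriors over signature bins", {
  case <- medremix_case()
  fit <- case$fit
  bins <- fit$window_id[order(-fit$posterior)][1:77]
  score <- methylation_score(fit, bins)
  expect_equal(score, sum(fit$posterior[match(bins, fit$window_id)]))
  expect_lte(score, 77)
  expect_error(methylation_score(fit, c(bins, "chrZ:0")), "chrZ:0")
  # degenerate posteriors hit the bounds
  fit2 <- fit
  fit2$posterior <- rep(1, length(fit$posterior))
  expect_equal(methylation_score(fit2, bins), 77)
  fit2$posterior <- rep(0, length(fit$posterior))
  expect_equal(methylation_score(fit2, bins), 0)
})

test_that("tumor samples outscore healthy samples on planted signature bins", {
  g <- medip_genome(3000)
  w <- build_windows(g, 300)
  sig_idx <- which(w$cpg >= 5)[1:77]
  sig_bins <- paste0(w$chrom[sig_idx], ":",
                     format(w$start[sig_idx], scientific = FALSE, trim = TRUE))
  truth_h <- methylation_truth(pi = 0.1)
  wins <- 0L
  for (s in 1:20) {
    sim_t <- simulate_medip_windows(g, methylation_truth(pi = 0.25), seed = 900 + s,
                                    windows = w)
    # force signature bins methylated in the tumor draw
    sim_t$windows$count[sig_idx] <- withr::with_seed(950 + s,
      rnbinom(77, size = 8, mu = exp(3 + 0.08 * w$cpg[sig_idx])))
    sim_h <- simulate_medip_windows(g, truth_h, seed = 920 + s, windows = w)
    bg_t <- fit_nonmethylated(sim_t$windows)
    bg_h <- fit_nonmethylated(sim_h$windows)
    sc_t <- methylation_score(em_fit(sim_t$windows, bg_t, tol = 1e-4), sig_bins)
    sc_h <- methylation_score(em_fit(sim_h$windows, bg_h, tol = 1e-4), sig_bins)
    wins <- wins + (sc_t > sc_h)
  }
  expect_equal(wins, 20L)
})

test_that("spike-in and enrichment QC follow their definitions", {
  expect_equal(qc_spikein(9311, 689), 0.9311)
  expect_equal(qc_spikein(1, 0), 1)
  expect_equal(qc_spikein(0, 5), 0)
  expect_error(qc_spikein(0, 0), "spike-in")
  comp <- list(n_c = 100, n_g = 100, n_cg = 25, len = 400)
  same <- qc_enrichment(comp, comp)
  expect_equal(same$relH, 1)
  expect_equal(same$GoGe, 1)
  # relH 50 vs 25 -> score 2
  smp <- list(n_c = 200, n_g = 200, n_cg = 200, len = 400)
  gen <- list(n_c = 200, n_g = 200, n_cg = 100, len = 400)
  expect_equal(qc_enrichment(smp, gen)$relH, 2)
  expect_error(qc_enrichment(list(n_c = 0, n_g = 1, n_cg = 0, len = 10), comp),
               "zero")
})
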