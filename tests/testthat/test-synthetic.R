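test_that("fragment simulation matches its mixture CDF oracle", {
  g <- genome_model("chr1", 1e7)
  # zero-variance single component: every length exact
  m0 <- fragment_length_model(data.frame(mean = 167, sd = 0, weight = 1),
                              n_fragments = 10)
  f0 <- simulate_fragments(m0, g, seed = 1)
  expect_true(all(f0$end - f0$start == 167))
  # two-component mixture: mass below 150 vs numeric CDF
  m <- fragment_length_model(data.frame(mean = c(120, 167), sd = c(10, 10),
                                        weight = c(0.3, 0.7)),
                             n_fragments = 1e5)
  f <- simulate_fragments(m, g, seed = 1)
  emp <- mean((f$end - f$start) <= 150)
  oracle <- fragment_length_cdf(m, 150.5)  # lengths are rounded to integers
  expect_lt(abs(emp - oracle), 0.01)
  # determinism
  expect_identical(simulate_fragments(m, g, seed = 2),
                   simulate_fragments(m, g, seed = 2))
  expect_error(simulate_fragments(m, genome_model(character(0), numeric(0))))
})

test_that("CNV count simulation hits its closed-form expectation", {
  g <- genome_model("chr1", 1e7)
  # no segments: expectation equals depth everywhere
  b0 <- simulate_cnv_counts(g, NULL, depth = 500, seed = 1)
  expect_true(all(b0$expected == 500))
  # multiplier 1 is indistinguishable from no event in expectation
  seg1 <- data.frame(chrom = "chr1", start = 0, end = 1e7,
                     multiplier = 1, tumor_fraction = 0.5)
  expect_true(all(simulate_cnv_counts(g, seg1, depth = 500, seed = 1)$expected == 500))
  # multiplier 1.5 at tumor fraction 0.1: mean ~ 1050 over 1e4 bins
  g2 <- genome_model("chr1", 1e9)
  seg <- data.frame(chrom = "chr1", start = 0, end = 1e9,
                    multiplier = 1.5, tumor_fraction = 0.1)
  b <- simulate_cnv_counts(g2, seg, depth = 1000, seed = 3, width = 1e5)
  expect_equal(nrow(b), 1e4)
  expect_lt(abs(mean(b$count) / 1050 - 1), 0.01)
  # overlapping segments rejected
  segs <- data.frame(chrom = "chr1", start = c(0, 5e6), end = c(6e6, 8e6),
                     multiplier = 1.5, tumor_fraction = 0.1)
  expect_error(simulate_cnv_counts(g, segs, depth = 10, seed = 1), "overlap")
})

test_that("cfMeDIP generator respects the latent mixture", {
  g <- medip_genome(20000)
  w <- build_windows(g, 300)
  # pi = 0: everything unmethylated; pi = 1: every CpG window methylated
  s0 <- simulate_medip_windows(g, methylation_truth(pi = 0), seed = 1, windows = w)
  expect_false(any(s0$latent))
  s1 <- simulate_medip_windows(g, methylation_truth(pi = 1), seed = 1, windows = w)
  expect_true(all(s1$latent[w$cpg > 0]))
  expect_false(any(s1$latent[w$cpg == 0]))  # identifiability assumption
  # pi = 0.3: empirical methylated fraction within binomial bounds
  s <- simulate_medip_windows(g, methylation_truth(pi = 0.3), seed = 7, windows = w)
  expect_lt(abs(mean(s$latent[w$cpg > 0]) - 0.3), 0.02)
  expect_error(methylation_truth(phi0 = -1), "dispersion")
})

test_that("methylation arrays plant the stated M-scale effect", {
  sim <- simulate_methylation_arrays(n_cohorts = 2, n_samples_per_cohort = 50,
                                     n_sites = 500, planted = 1:40,
                                     effect_size = 4, seed = 2)
  expect_true(all(sim$beta > 0 & sim$beta < 1))
  m <- mvalues(sim$beta)
  d <- rowMeans(m[, sim$labels == "cohort1"]) -
    rowMeans(m[, sim$labels == "cohort2"])
  expect_lt(abs(mean(d[1:40]) - 4), 0.3)
  # effect 0: planted indistinguishable from background
  sim0 <- simulate_methylation_arrays(2, 20, 500, planted = 1:40,
                                      effect_size = 0, seed = 2)
  m0 <- mvalues(sim0$beta)
  d0 <- rowMeans(m0[, sim0$labels == "cohort1"]) -
    rowMeans(m0[, sim0$labels == "cohort2"])
  expect_lt(abs(mean(d0[1:40])), 0.3)
  expect_error(simulate_methylation_arrays(2, 1, 10), "2 samples")
})

test_that("metric trajectories are constant without noise or slope", {
  fx <- make_clinical_fixture()
  params <- default_trajectory_params()
  params$slope <- 0
  params$noise_sd <- 0
  ts <- simulate_metric_timeseries(fx, params, seed = 1, intercept_sd = 0)
  expect_true(all(abs(ts$metrics$cn_z) < 1e-12))
})

test_that("relapser trajectories rise above resting level before relapse", {
  fx <- make_clinical_fixture()
  params <- default_trajectory_params()
  params$noise_sd <- 0
  ts <- simulate_metric_timeseries(fx, params, seed = 1, intercept_sd = 0)
  m <- merge(ts$metrics, ts$labels[, c("patient_id", "timepoint", "month")])
  rel <- fx$records[fx$records$relapse == "yes", ]
  for (p in rel$patient_id) {
    rows <- m[m$patient_id == p & m$month > 0, ]
    final <- rows[which.max(rows$month), ]
    expect_gt(final$cn_z, params$baseline[params$metric == "cn_z"])
  }
})

test_that("generators are bit-for-bit reproducible under a fixed seed", {
  g <- toy_genome()
  expect_identical(simulate_cnv_counts(g, NULL, 100, seed = 5),
                   simulate_cnv_counts(g, NULL, 100, seed = 5))
  tr <- methylation_truth()
  w <- build_windows(medip_genome(2000), 300)
  expect_identical(simulate_medip_windows(medip_genome(2000), tr, 5, windows = w),
                   simulate_medip_windows(medip_genome(2000), tr, 5, windows = w))
  expect_identical(simulate_methylation_arrays(2, 5, 50, seed = 5),
                   simulate_methylation_arrays(2, 5, 50, seed = 5))
})
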