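make_dist <- function(lengths, counts, range = c(10, 500)) {
  g <- genome_model("c", 1e6)
  frag <- fragment_set(rep("c", sum(counts)), rep(0, sum(counts)),
                       rep(lengths, counts), g)
  size_distribution(frag, range)
}

test_that("short-fragment proportion follows its definition", {
  d <- make_dist(c(100, 200), c(5, 5))
  expect_equal(short_fragment_proportion(d), 0.5)
  d2 <- make_dist(c(160, 170, 180), c(3, 3, 3))
  expect_equal(short_fragment_proportion(d2), 0)
  expect_error(short_fragment_proportion(make_dist(300, 5)), "denominator")
  # mixture generator: 30% short-mode mass, against the mixture CDF oracle
  m <- tumor_length_model(short_weight = 0.3, n = 1e5)
  f <- simulate_fragments(m, genome_model("chr1", 1e7), seed = 2)
  cdf <- fragment_length_cdf(m, c(9.5, 150.5, 250.5))
  oracle <- (cdf[2] - cdf[1]) / (cdf[3] - cdf[1])
  expect_lt(abs(short_fragment_proportion(size_distribution(f)) - oracle), 0.01)
})

test_that("size z-score is zero at the panel mean and aggregates correctly", {
  g <- genome_model("chr1", 1e7)
  d <- size_distribution(simulate_fragments(healthy_length_model(n = 2e4), g, seed = 101))
  p <- d$count / d$total
  names(p) <- as.character(d$length)
  # symmetric panel around the sample's own proportions: all z exactly 0
  delta <- 1e-3
  panel0 <- build_healthy_panel(list(p[as.character(90:150)] - delta,
                                     p[as.character(90:150)] + delta))
  z <- size_zscore(d, panel0)
  expect_equal(z$aggregate, 0)
  expect_equal(z$n_features, 61L)
  # real panel: a tumor-shifted sample scores above a healthy one
  dists <- lapply(1:6, function(i)
    size_distribution(simulate_fragments(healthy_length_model(n = 2e4), g, seed = 100 + i)))
  feats <- lapply(dists, function(di) {
    pi <- di$count / di$total
    names(pi) <- as.character(di$length)
    pi[as.character(90:150)]
  })
  panel <- build_healthy_panel(feats)
  tum <- size_distribution(simulate_fragments(tumor_length_model(0.35, 2e4), g, seed = 9))
  expect_gt(size_zscore(tum, panel)$aggregate,
            size_zscore(dists[[1]], panel)$aggregate)
})

test_that("ratio profile scales 5 Mb ratios to mean 0, unit SD", {
  g <- toy_genome()
  frag <- simulate_fragments(healthy_length_model(n = 1.5e5), g, seed = 1)
  prof <- suppressWarnings(fragment_ratio_profile(frag, g))
  r <- prof$bins5$ratio_scaled
  expect_lt(abs(mean(r, na.rm = TRUE)), 1e-9)
  expect_lt(abs(sd(r, na.rm = TRUE) - 1), 1e-9)
  expect_equal(nrow(prof$bins5), 12L)  # 4 x 5 Mb per 20 Mb chromosome
})

test_that("ratio profile is invariant to uniform depth scaling", {
  g <- toy_genome()
  frag <- simulate_fragments(healthy_length_model(n = 5e4), g, seed = 3)
  doubled <- fragment_set(rep(frag$chrom, 2), rep(frag$start, 2),
                          rep(frag$end, 2), g)
  p1 <- suppressWarnings(fragment_ratio_profile(frag, g))
  p2 <- suppressWarnings(fragment_ratio_profile(doubled, g))
  expect_equal(p2$bins5$ratio_scaled, p1$bins5$ratio_scaled, tolerance = 1e-9)
})

test_that("a planted 8q gain with short tumor fragments raises 8q ratios", {
  g <- toy_genome()
  bg <- simulate_fragments(healthy_length_model(n = 1.2e5), g, seed = 5)
  # tumor-derived short fragments concentrated on chr8 q arm
  tum_arm <- simulate_fragments(
    fragment_length_model(data.frame(mean = c(120, 145), sd = c(10, 8),
                                     weight = c(0.6, 0.4)),
                          n_fragments = 6000),
    genome_model("chr8", 1e7), seed = 6)
  tum_arm$start <- tum_arm$start + 1e7
  tum_arm$end <- tum_arm$end + 1e7
  frag <- fragment_set(c(bg$chrom, tum_arm$chrom), c(bg$start, tum_arm$start),
                       c(bg$end, tum_arm$end), g)
  prof <- suppressWarnings(fragment_ratio_profile(frag, g))
  b5 <- prof$bins5
  on8q <- b5$chrom == "chr8" & b5$start >= 1e7
  expect_gt(mean(b5$ratio_scaled[on8q]), mean(b5$ratio_scaled[!on8q]))
})

test_that("targeted ratio z-scores select overlapping bins only", {
  g <- toy_genome()
  frags <- lapply(1:6, function(i)
    simulate_fragments(healthy_length_model(n = 8e4), g, seed = 200 + i))
  profs <- lapply(frags, function(f) suppressWarnings(fragment_ratio_profile(f, g)))
  feats100 <- lapply(profs, function(p) {
    v <- p$bins100$ratio_scaled
    names(v) <- p$bins100$bin_id
    v[!is.na(v)]
  })
  panel100 <- build_healthy_panel(feats100)
  prof <- profs[[1]]
  # a single 1 bp locus inside one bin selects exactly that bin
  one <- targeted_profile_zscore(prof,
                                 data.frame(chrom = "chr3", start = 150000, end = 150001),
                                 panel100)
  expect_equal(one$n_features, 1L)
  # loci covering everything reproduce the genome-wide 100 kb result
  all_loci <- data.frame(chrom = g$chroms$chrom, start = 0, end = g$chroms$length)
  full <- targeted_profile_zscore(prof, all_loci, panel100)
  v <- prof$bins100$ratio_scaled
  names(v) <- prof$bins100$bin_id
  v <- v[!is.na(v)]
  ref <- zscore_summary(v[intersect(panel100$features[!panel100$flagged], names(v))],
                        panel100)
  expect_equal(full$aggregate, ref$aggregate, tolerance = 1e-9)
  expect_error(targeted_profile_zscore(prof, all_loci[0, ], panel100), "nonempty")
})

test_that("site coverage is flat for uniform fragments and dips when depleted", {
  g <- genome_model("chr1", 2e7)
  frag <- simulate_fragments(healthy_length_model(n = 3e5), g, seed = 8)
  sites <- data.frame(chrom = "chr1", center = seq(2e6, 18e6, by = 2e5))
  prof <- site_coverage(frag, sites)
  expect_lt(abs(prof$central - 1), 0.15)
  expect_equal(mean(prof$depth[abs(prof$offset) >= 750]), 1, tolerance = 1e-9)
  # remove fragments within 200 bp of any site center: central < flank level
  keep <- rep(TRUE, nrow(frag))
  for (ctr in sites$center) {
    keep <- keep & !(frag$end > ctr - 200 & frag$start < ctr + 200)
  }
  depleted <- fragment_set(frag$chrom[keep], frag$start[keep], frag$end[keep], g)
  prof_dep <- site_coverage(depleted, sites)
  expect_lt(prof_dep$central, 0.5)
  # one fragment overlapping one center: depth 1 at covered offsets
  single <- fragment_set("chr1", 1e6 - 50, 1e6 + 50, g)
  p1 <- site_coverage(single, data.frame(chrom = "chr1", center = 1e6 + 900),
                      flank = 1000)
  raw_covered <- p1$depth[p1$offset >= -950 & p1$offset <= -851]
  expect_true(all(raw_covered > 0))
  expect_equal(length(unique(raw_covered)), 1L)
})

test_that("central-coverage z-score arithmetic and sign convention", {
  panel <- build_healthy_panel(list(c(central = 0.9), c(central = 1.0),
                                    c(central = 1.1)))
  mu <- panel$mean["central"]; s <- panel$sd["central"]
  expect_equal(central_coverage_zscore(unname(mu), panel), 0)
  expect_equal(central_coverage_zscore(unname(mu + 2 * s), panel), 2)
  expect_lt(central_coverage_zscore(0.5, panel), 0)  # dip -> negative
  flat <- build_healthy_panel(list(c(central = 1), c(central = 1)))
  expect_error(central_coverage_zscore(1, flat), "variance")
})
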