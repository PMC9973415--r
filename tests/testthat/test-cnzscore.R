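test_that("GC correction removes a planted linear trend", {
  g <- genome_model("chr1", 1e8)
  b <- simulate_cnv_counts(g, NULL, depth = 1000, seed = 2)
  slope0 <- coef(lm(b$count ~ b$gc))[2]
  # plant a strong linear GC bias
  b$count <- b$count + round(2000 * (b$gc - mean(b$gc)))
  planted_slope <- coef(lm(b$count ~ b$gc))[2]
  corr <- gc_correct_counts(b)
  resid_slope <- coef(lm(corr$count_corr ~ corr$gc))[2]
  expect_lt(abs(resid_slope / planted_slope), 0.05)
  # GC-independent counts pass through almost unchanged
  b2 <- simulate_cnv_counts(g, NULL, depth = 1000, seed = 3)
  corr2 <- gc_correct_counts(b2)
  expect_lt(max(abs(corr2$count_corr - b2$count)) / 1000, 0.15)
  # all-zero counts stay zero
  b3 <- b2; b3$count <- rep(0L, nrow(b3))
  expect_true(all(gc_correct_counts(b3)$count_corr == 0))
  expect_error(gc_correct_counts(b2[1:10, ]), "50")
})

test_that("copy ratio recovers the closed-form CNV dilution", {
  g <- toy_genome_bg()
  panels <- healthy_cn_panels(g, 101:110)
  # sample equal to the panel median profile: a flat ratio profile whose
  # level is the (near-zero) log of the profile's own median renormalizer
  med <- panels$counts$median
  bins <- build_windows(g, 1e6)
  bins$count_corr <- unname(
    med[paste0(bins$chrom, ":", format(bins$start, scientific = FALSE, trim = TRUE))])
  r0 <- copy_ratio(bins, panels$counts)
  expect_lt(sd(r0$log2_ratio, na.rm = TRUE), 1e-12)
  expect_lt(max(abs(r0$log2_ratio), na.rm = TRUE), 0.02)
  # monosomy 3 at tumor fraction 0.2: mean chr3 ratio ~ log2(0.9)
  seg <- data.frame(chrom = "chr3", start = 0, end = 2e7,
                    multiplier = 0.5, tumor_fraction = 0.2)
  tum <- suppressWarnings(gc_correct_counts(
    simulate_cnv_counts(g, seg, depth = 1000, seed = 9)))
  r <- copy_ratio(tum, panels$counts)
  expect_lt(abs(mean(r$log2_ratio[r$chrom == "chr3"], na.rm = TRUE) - log2(0.9)),
            0.02)
})

test_that("arm-weighted z-score arithmetic matches a brute-force pass", {
  g <- toy_genome()
  panels <- healthy_cn_panels(g, 301:310)
  seg <- rbind(
    data.frame(chrom = "chr3", start = 0, end = 2e7, multiplier = 0.5,
               tumor_fraction = 0.1),
    data.frame(chrom = "chr8", start = 1e7, end = 2e7, multiplier = 1.5,
               tumor_fraction = 0.1)
  )
  tum <- suppressWarnings(gc_correct_counts(
    simulate_cnv_counts(g, seg, depth = 1000, seed = 21)))
  ratio <- copy_ratio(tum, panels$counts)
  cz <- cn_zscore(ratio, panels$ratios)
  # brute force: per-arm |sum z / sqrt(n)| and bin-count weights
  panel <- panels$ratios
  sub <- ratio[!ratio$masked & ratio$bin_id %in% panel$features[!panel$flagged], ]
  z <- (sub$log2_ratio - panel$mean[sub$bin_id]) / panel$sd[sub$bin_id]
  key <- paste0(sub$chrom, sub$arm)
  brute <- sapply(split(z, key), function(za) abs(sum(za) / sqrt(length(za))))
  n_a <- sapply(split(z, key), length)
  brute_score <- sum((n_a / sum(n_a)) * brute[names(n_a)])
  expect_equal(cz$weighted_score, brute_score, tolerance = 1e-9)
  expect_equal(sum(cz$arms$weight), 1)
  # reordering bins changes nothing
  perm <- withr::with_seed(1, sample(nrow(ratio)))
  cz_perm <- cn_zscore(ratio[perm, ], panels$ratios)
  expect_equal(cz_perm$weighted_score, cz$weighted_score, tolerance = 1e-12)
})

test_that("weighted score grows with tumor fraction and detects tf = 0.1", {
  g <- toy_genome()
  panels <- healthy_cn_panels(g, 401:412)
  score_at <- function(tf, seed) {
    segs <- rbind(
      data.frame(chrom = "chr3", start = 0, end = 2e7, multiplier = 0.5,
                 tumor_fraction = tf),
      data.frame(chrom = "chr8", start = 1e7, end = 2e7, multiplier = 1.5,
                 tumor_fraction = tf)
    )
    tum <- suppressWarnings(gc_correct_counts(
      simulate_cnv_counts(g, if (tf > 0) segs else NULL, depth = 1000, seed = seed)))
    cn_weighted_score(tum, panels)
  }
  seeds <- 1:20
  s0 <- vapply(seeds, function(s) score_at(0, 500 + s), numeric(1))
  s05 <- vapply(seeds, function(s) score_at(0.05, 500 + s), numeric(1))
  s10 <- vapply(seeds, function(s) score_at(0.10, 500 + s), numeric(1))
  expect_gt(mean(s05), mean(s0))
  expect_gt(mean(s10), mean(s05))
  # healthy 90th percentile from leave-one-out panel scores
  healthy_scores <- vapply(seeds, function(s) score_at(0, 700 + s), numeric(1))
  thr <- healthy_threshold_classify(0, healthy_scores)$threshold
  expect_gte(sum(s10 > thr), 19L)
})

test_that("tumor-fraction positivity is strictly greater than 0.03", {
  expect_true(classify_tumor_fraction(0.074))
  expect_false(classify_tumor_fraction(0.03))
  expect_false(classify_tumor_fraction(0))
  expect_equal(classify_tumor_fraction(c(0.02, 0.031)), c(FALSE, TRUE))
  expect_error(classify_tumor_fraction(1.2), "\\[0, 1\\]")
})

test_that("short-fragment mode refuses below 0.1X post-pruning coverage", {
  g <- genome_model("chr1", 1e6)
  # 2000 fragments x 100 bp = 0.2X
  frag <- fragment_set(rep("chr1", 2000), seq(0, 999000, length.out = 2000),
                       seq(0, 999000, length.out = 2000) + 100, g)
  res <- short_fragment_mode(frag, g)
  expect_equal(res$status, "ok")
  expect_equal(res$coverage, 0.2)
  # 0.05X: refusal status, not an error
  res2 <- short_fragment_mode(frag[1:500, ], g)
  expect_equal(res2$status, "refused")
  expect_equal(res2$coverage, 0.05)
  empty <- fragment_set(character(0), numeric(0), numeric(0))
  expect_equal(short_fragment_mode(empty, g)$status, "refused")
})
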