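# Variance-adaptive segmentation, calibration, subdivision, exclusion.

test_that("variance profile matches hand computation and handles degenerate input", {
  # identical samples -> all-zero profile
  st <- toy_stack(rbind(c(1, 5, 2, 8), c(1, 5, 2, 8)))
  expect_equal(variance_profile(st, 8)$values, rep(0, 3))
  # hand case: log2 rows (3,4,4) and (4,4,3); diffs (1,0) and (0,-1);
  # sample variances (0.5, 0.5)
  st2 <- toy_stack(rbind(c(0, 8, 8), c(8, 8, 0)))
  expect_equal(variance_profile(st2, 8)$values, c(0.5, 0.5))
  # single sample is an error
  expect_error(variance_profile(toy_stack(matrix(1:4, 1)), 8), "2 samples")
})

test_that("variance profile equals a naive two-loop oracle", {
  set.seed(1)
  vals <- matrix(rpois(256 * 60, 20), 256, 60)
  st <- toy_stack(vals)
  prof <- variance_profile(st, 8)$values
  lg <- log2(vals + 8)
  oracle <- numeric(59)
  for (i in 1:59) {
    d <- numeric(256)
    for (s in 1:256) d[s] <- lg[s, i + 1] - lg[s, i]
    oracle[i] <- var(d)
  }
  expect_lt(max(abs(prof - oracle)), 1e-10)
})

test_that("segmentation follows the greedy cumulative rule", {
  # all-zero profile: one bin spanning the region
  expect_equal(segment_region(rep(0, 9), 1), cbind(start = 0, end = 10))
  # spec-style hand trace: (0.5 x4), threshold 1 -> bins of sizes 3 and 2
  b <- segment_region(rep(0.5, 4), 1.0)
  expect_equal(b[, 2] - b[, 1], c(3, 2), ignore_attr = TRUE)
  # trigger base is included in the closing bin; accumulator resets to 0
  b2 <- segment_region(c(2, 0.1, 0.1, 2), 1.0)
  expect_equal(unname(b2[1, ]), c(0, 2))
})

test_that("segmentation equals the literal greedy loop on random profiles", {
  set.seed(7)
  for (rep_i in 1:25) {
    p <- rexp(sample(20:400, 1), rate = runif(1, 0.5, 5))
    p[sample(length(p), length(p) %/% 4)] <- 0   # flat stretches incl. ties
    th <- runif(1, 0.1, 5)
    expect_equal(unname(segment_region(p, th)),
                 unname(greedy_segment_oracle(p, th)))
  }
})

test_that("bin count is non-increasing in the threshold", {
  set.seed(8)
  for (rep_i in 1:50) {
    p <- rexp(sample(50:300, 1))
    th <- runif(1, 0.05, 2)
    n1 <- nrow(segment_region(p, th))
    n2 <- nrow(segment_region(p, 2 * th))
    expect_gte(n1, n2)
  }
})

test_that("higher-mass profiles receive at least as many bins", {
  set.seed(9)
  p <- rexp(200)
  expect_gte(nrow(segment_region(2 * p, 1)), nrow(segment_region(p, 1)))
  expect_gte(nrow(segment_region(p, 1)), nrow(segment_region(p / 3, 1)))
})

test_that("oversized bins subdivide into balanced parts", {
  # boundary: width exactly max is unchanged
  expect_equal(subdivide_bins(cbind(0, 1024), 1024),
               cbind(start = 0, end = 1024))
  # 2500 -> 834, 833, 833 (longer parts first)
  b <- subdivide_bins(cbind(0, 2500), 1024)
  expect_equal(b[, 2] - b[, 1], c(834, 833, 833), ignore_attr = TRUE)
  # 3000 -> 1000 x 3
  b <- subdivide_bins(cbind(100, 3100), 1024)
  expect_equal(b[, 2] - b[, 1], rep(1000, 3), ignore_attr = TRUE)
  expect_equal(unname(b[1, 1]), 100)
  # contiguity preserved across a mixed scheme
  b <- subdivide_bins(rbind(c(0, 5000), c(5000, 5100), c(5100, 9000)), 1024)
  expect_equal(b[-1, 1], b[-nrow(b), 2], ignore_attr = TRUE)
  expect_true(all(b[, 2] - b[, 1] >= 1 & b[, 2] - b[, 1] <= 1024))
})

test_that("foreign-exon exclusion matches brute force including 1-base overlap", {
  region <- toy_region(span = 1000,
                       foreign_exons = rbind(c(199, 300), c(650, 700)))
  bins <- cbind(seq(0, 900, by = 100), seq(100, 1000, by = 100))
  split <- exclude_foreign_exonic(bins, region)
  # brute force: any shared base
  overlap <- sapply(seq_len(nrow(bins)), function(i)
    any(bins[i, 1] < region$foreign_exons[, 2] &
        region$foreign_exons[, 1] < bins[i, 2]))
  expect_equal(split$kept, bins[!overlap, , drop = FALSE], ignore_attr = TRUE)
  expect_equal(split$removed, bins[overlap, , drop = FALSE], ignore_attr = TRUE)
  # bin [100,200) vs exon starting at 199: removed (1-base overlap)
  expect_true(any(split$removed[, 1] == 100))
  # empty foreign exons: nothing removed
  split0 <- exclude_foreign_exonic(bins, toy_region(span = 1000))
  expect_equal(nrow(split0$removed), 0)
})

test_that("adaptive scheme partitions the region and respects the width cap", {
  set.seed(10)
  vals <- matrix(rpois(40 * 3000, 15), 40, 3000)
  region <- toy_region(span = 3000, foreign_exons = rbind(c(1200, 1300)))
  prof <- variance_profile(toy_stack(vals), 8)
  scheme <- adaptive_bin_scheme(region, prof, threshold = 0.5,
                                max_bin_size = 256)
  expect_partition(scheme, region)
  w <- scheme$bins[, 2] - scheme$bins[, 1]
  expect_true(all(w >= 1 & w <= 256))
  expect_true(nrow(scheme$removed_bins) > 0)
  # removed bins all intersect the foreign exon
  expect_true(all(scheme$removed_bins[, 1] < 1300 &
                  scheme$removed_bins[, 2] > 1200))
})

test_that("uniform binning tiles the region and shares the exclusion path", {
  region <- toy_region(span = 100, flank = 10,
                       foreign_exons = rbind(c(35, 45)))
  sch <- uniform_bins(region, 30)
  expect_partition(sch, region)
  all_w <- diff(sort(c(sch$bins[, 1], sch$removed_bins[, 1],
                       region$region_end)))
  expect_equal(sort(unname(all_w), decreasing = TRUE), c(30, 30, 30, 10))
  # exclusion identical to the adaptive path on the same bins
  bins <- rbind(sch$bins, sch$removed_bins)
  bins <- bins[order(bins[, 1]), ]
  split <- exclude_foreign_exonic(bins, region)
  expect_equal(split$kept, sch$bins[order(sch$bins[, 1]), ], ignore_attr = TRUE)
  # width >= span: one bin
  expect_equal(nrow(uniform_bins(toy_region(span = 50), 500)$bins), 1)
})

test_that("threshold calibration hits the closed form on a uniform profile", {
  # single gene, uniform profile summing to S -> threshold ~ S / target
  L <- 4097
  vals <- matrix(0, 2, L)
  region <- toy_region(span = L, flank = 10)
  # build a stack whose profile is exactly constant: alternate 0/8 rows give
  # profile 0.5 everywhere
  vals[1, ] <- rep(c(0, 8), length.out = L)
  vals[2, ] <- rep(c(8, 0), length.out = L)
  src <- memory_coverage_source(list(g1 = toy_stack(vals)))
  regions <- list(g1 = region)
  th <- calibrate_threshold(regions, src, target_mean_bins = 64,
                            n_binning_samples = 2, seed = 1)
  S <- sum(variance_profile(toy_stack(vals), 8)$values)
  expect_equal(as.numeric(th), S / 64, tolerance = 0.1)
  mb <- attr(th, "mean_bins")
  expect_lt(abs(mb / 64 - 1), 0.02)
  # monotone bracket: mean bins at th/10 >= target >= mean bins at th*10
  prof <- variance_profile(toy_stack(vals), 8)$values
  expect_gte(nrow(segment_region(prof, as.numeric(th) / 10)), 64)
  expect_lte(nrow(segment_region(prof, as.numeric(th) * 10)), 64)
})

test_that("calibration errors on all-zero coverage", {
  vals <- matrix(5, 3, 500)   # constant across samples -> zero profile
  src <- memory_coverage_source(list(g1 = toy_stack(vals)))
  expect_error(
    calibrate_threshold(list(g1 = toy_region(span = 500)), src,
                        target_mean_bins = 16, seed = 1),
    "coverage")
})

test_that("scheme BED round-trips exactly, removed bins included", {
  region <- toy_region(span = 2000, foreign_exons = rbind(c(500, 600)))
  set.seed(11)
  prof <- list(gene_id = "g1", values = rexp(1999, 2))
  sch <- adaptive_bin_scheme(region, prof, threshold = 3, max_bin_size = 128,
                             pseudocount = 8, seed = 11L)
  uni <- uniform_bins(toy_region("g2", span = 300), 90)
  f <- withr::local_tempfile(fileext = ".bed")
  write_scheme(list(g1 = sch, g2 = uni), f)
  back <- read_scheme(f)
  expect_equal(back$g1, sch)
  expect_equal(back$g2, uni)
  expect_true(nrow(back$g1$removed_bins) > 0)
  # single-bin scheme round-trips
  one <- bin_scheme("g3", "chr2", "-", cbind(10, 20),
                    provenance = list(method = "uniform", bin_width = 10))
  write_scheme(list(g3 = one), f)
  expect_equal(read_scheme(f)$g3, one)
})
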