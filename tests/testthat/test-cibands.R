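test_that("null bands are symmetric and shrink with depth and bulk size", {
  curve <- null_delta_quantiles(bulk_size = 20, depth_grid = c(5, 15, 30, 60),
                                n_replicates = 10000, seed = 7)
  expect_true(all(curve$lower <= 0 & curve$upper >= 0))
  expect_true(all(abs(curve$upper + curve$lower) <= 0.07))  # symmetric within MC error
  expect_true(all(diff(curve$upper) <= 1e-9 + 0.02))        # non-increasing (MC slack)
  # law of large numbers: huge bulk and depth pin the null delta near 0
  tight <- null_delta_quantiles(bulk_size = 20000, depth_grid = 20000,
                                n_replicates = 4000, seed = 8)
  expect_lt(tight$upper, 0.02)
  expect_gt(tight$lower, -0.02)
  expect_error(null_delta_quantiles(depth_grid = c(0, 10)), "positive")
})

test_that("the band is conservative: attained coverage is at least nominal", {
  curve <- null_delta_quantiles(bulk_size = 20, depth_grid = 15,
                                n_replicates = 10000, seed = 21)
  set.seed(22)
  f1 <- rbinom(10000, 20, 0.5) / 40
  f2 <- rbinom(10000, 20, 0.5) / 40
  delta <- rbinom(10000, 15, f1) / 15 - rbinom(10000, 15, f2) / 15
  coverage <- mean(delta >= curve$lower & delta <= curve$upper)
  mc_se <- sqrt(0.95 * 0.05 / 10000)
  expect_gte(coverage, 0.95 - 3 * mc_se)
})

test_that("nearest-depth band lookup matches a linear-search oracle", {
  curve <- null_delta_quantiles(bulk_size = 20, depth_grid = 1:100,
                                n_replicates = 2000, seed = 3)
  set.seed(5)
  for (i in 1:5) {
    depths <- runif(200, 0.5, 120)
    got <- threshold_at_depth(curve, depths)
    oracle_i <- vapply(depths, function(d) which.min(abs(curve$depth - d)),
                       integer(1))
    expect_equal(got$lower, curve$lower[oracle_i])
    expect_equal(got$upper, curve$upper[oracle_i])
  }
})

test_that("window flagging is strict-outside and respects eligibility", {
  curve <- null_delta_quantiles(bulk_size = 20, depth_grid = 15,
                                n_replicates = 10000, seed = 11)
  prof <- data.frame(chrom = "A09", start = c(1, 1001, 2001, 3001),
                     end = c(1000, 2000, 3000, 4000), n_snps = c(50, 50, 50, 2),
                     mean_depth = 15,
                     index_pool1 = c(0.5, 1, 1, 1), index_pool2 = c(0.5, 0, 0, 0),
                     delta = c(0, 1, 1, 1),
                     partial = FALSE, eligible = c(TRUE, TRUE, TRUE, FALSE))
  fl <- flag_windows(prof, curve)
  expect_false(fl$significant[1])        # delta 0 is never significant
  expect_true(all(fl$significant[2:3]))  # delta 1 clears any finite band at 15x
  expect_false(fl$significant[4])        # too few SNPs
  expect_error(flag_windows(prof, curve[0, ]), "empty")
})

test_that("raising the confidence never increases the significant-window count", {
  g <- toy_genome(n_snps = 400, lengths = c(A09 = 1e6), morgans = c(A09 = 0.5))
  d <- cross_design(selection_pos = g$snp_positions$A09[200],
                    population_size = 200, bulk_size = 20)
  pop <- simulate_cross(g, d, seed = 2)
  bulks <- make_bulks(pop, seed = 3)
  ad <- merge_allele_depths(list(
    simulate_pool_depths(bulks$brown, g, seed = 4, sample_name = "b"),
    simulate_pool_depths(bulks$yellow, g, seed = 5, sample_name = "y")))
  idx <- toy_idx(pos = ad$pos, index1 = NA, index2 = NA)
  idx$depth1 <- ad$b.ref + ad$b.alt; idx$index1 <- compute_snp_index(ad$b.alt, idx$depth1)
  idx$depth2 <- ad$y.ref + ad$y.alt; idx$index2 <- compute_snp_index(ad$y.alt, idx$depth2)
  idx <- apply_filters(idx)
  prof <- sliding_window_profile(idx, 1e5, 1e4, 5, c(A09 = 1e6))
  n_sig <- vapply(c(0.90, 0.95, 0.99), function(cf) {
    cu <- null_delta_quantiles(bulk_size = 20, depth_grid = 1:40,
                               n_replicates = 4000, confidence = cf, seed = 9)
    sum(flag_windows(prof, cu)$significant)
  }, numeric(1))
  expect_true(all(diff(n_sig) <= 0))
})

test_that("interval extraction merges runs exactly like a run-length oracle", {
  # abutting fixed-width windows: candidate spans equal significant runs
  rl_oracle <- function(flags, starts, width, gap = 0) {
    r <- rle(flags)
    ends_i <- cumsum(r$lengths); starts_i <- ends_i - r$lengths + 1
    iv <- data.frame(s = starts[starts_i[r$values]],
                     e = starts[ends_i[r$values]] + width - 1)
    if (nrow(iv) <= 1 || gap == 0) return(iv)
    keep <- iv[1, , drop = FALSE]
    for (j in 2:nrow(iv)) {
      if (iv$s[j] - keep$e[nrow(keep)] - 1 <= gap) keep$e[nrow(keep)] <- iv$e[j]
      else keep <- rbind(keep, iv[j, ])
    }
    keep
  }
  set.seed(17)
  for (i in 1:1000) {
    n <- sample(5:60, 1); width <- sample(c(100, 250), 1)
    starts <- seq(1, by = width, length.out = n)
    flags <- runif(n) < 0.35
    gap <- sample(c(0, 100, 500), 1)
    prof <- data.frame(chrom = "A09", start = starts, end = starts + width - 1,
                       n_snps = 10, mean_depth = 15, index_pool1 = 0.5,
                       index_pool2 = 0.25, delta = ifelse(flags, 0.5, 0),
                       partial = FALSE, eligible = TRUE, significant = flags)
    got <- extract_candidate_intervals(prof, merge_gap_bp = gap)
    oracle <- rl_oracle(flags, starts, width, gap)
    expect_equal(nrow(got), nrow(oracle))
    if (nrow(got)) {
      expect_equal(got$start, oracle$s)
      expect_equal(got$end, oracle$e)
    }
  }
})

test_that("no significant window yields an empty interval list", {
  prof <- data.frame(chrom = "A09", start = 1, end = 100, n_snps = 10,
                     mean_depth = 15, index_pool1 = 0.5, index_pool2 = 0.5,
                     delta = 0, partial = FALSE, eligible = TRUE,
                     significant = FALSE)
  expect_equal(nrow(extract_candidate_intervals(prof)), 0)
})

test_that("threshold curves and candidate BEDs round-trip through disk", {
  curve <- null_delta_quantiles(bulk_size = 20, depth_grid = c(10, 20),
                                n_replicates = 2000, seed = 13)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_threshold_curve(curve, path)
  back <- read_threshold_curve(path)
  expect_equal(as.data.frame(back), as.data.frame(curve))
  expect_equal(attr(back, "confidence"), 0.95)

  iv <- data.frame(chrom = "A09", start = c(17830001, 20530001),
                   end = c(18930000, 20990000), peak_delta = c(-0.5, -0.3))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_intervals_bed(iv, bed)
  back_iv <- read_intervals_bed(bed)
  expect_equal(back_iv$start, iv$start)   # 0-based half-open on disk, 1-based back
  expect_equal(back_iv$end, iv$end)
})
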