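test_that("genome and design constructors enforce their invariants", {
  expect_error(genome_spec(data.frame(name = character(), length = numeric()),
                           list(), numeric()), "at least one chromosome")
  expect_error(genome_at(c(10, 10)), "strictly increasing")
  expect_error(genome_at(c(10, 2e6)), "outside")
  expect_error(cross_design(bulk_size = 50, population_size = 40), "bulk_size")
  expect_error(pool_depth_model(error_rate = 0.7), "error_rate")
  expect_error(simulate_cross(genome_at(c(100, 200)),
                              cross_design(selection_pos = 150)),
               "not a SNP position")
  expect_error(simulate_cross(genome_at(c(100, 200)),
                              cross_design(selection_chrom = "A03",
                                           selection_pos = 100)),
               "not in genome")
})

test_that("zero recombination leaves whole-chromosome haplotypes in 1:1 proportion", {
  g <- genome_spec(data.frame(name = "A09", length = 1e6),
                   list(A09 = seq(1e4, 9.9e5, by = 1e4)),
                   c(A09 = 0))
  d <- cross_design(selection_pos = 5e5, population_size = 600, bulk_size = 20)
  pop <- simulate_cross(g, d, seed = 7)
  m <- pop$donor$A09
  # each plant is heterozygous across the whole chromosome or nowhere
  expect_true(all(rowSums(m) %in% c(0, ncol(m))))
  frac_het <- mean(rowSums(m) > 0)
  expect_gt(frac_het, 0.4); expect_lt(frac_het, 0.6)
  expect_identical(pop$phenotype, ifelse(m[, match(5e5, g$snp_positions$A09)],
                                         "brown", "yellow"))
})

test_that("unselected BC1 is Mendelian: heterozygote fraction 0.5 per SNP", {
  g <- toy_genome(n_snps = 100)
  d <- cross_design(n_backcrosses = 1, selection_chrom = "A09",
                    selection_pos = g$snp_positions$A09[1],
                    population_size = 4000, bulk_size = 20)
  pop <- simulate_cross(g, d, seed = 3)
  het <- mean(colMeans(pop$donor$A02))  # chromosome unlinked to the locus
  se <- sqrt(0.25 / (4000 * 1))         # per-locus se; loci correlated, be loose
  expect_lt(abs(het - 0.5), 0.05)
  expect_equal(mean(pop$phenotype == "brown"), 0.5, tolerance = 0.1)
})

test_that("crossover count per gamete is Poisson with the map length as mean", {
  g <- genome_spec(data.frame(name = "A09", length = 1e6),
                   list(A09 = seq(2000, 998000, length.out = 500)),
                   c(A09 = 1))          # 1 Morgan
  d <- cross_design(n_backcrosses = 1, selection_pos = g$snp_positions$A09[1],
                    population_size = 10000, bulk_size = 20)
  pop <- simulate_cross(g, d, seed = 11)
  m <- pop$donor$A09
  switches <- rowSums(m[, -1] != m[, -ncol(m)])
  expect_lt(abs(mean(switches) - 1.0), 0.03)
})

test_that("heterozygosity on an unselected chromosome decays as 2^-n backcrosses", {
  g <- toy_genome(n_snps = 60)
  d <- cross_design(n_backcrosses = 4, selection_chrom = "A09",
                    selection_pos = g$snp_positions$A09[50],
                    population_size = 60, bulk_size = 5)
  per_seed <- vapply(1:250, function(s)
    mean(simulate_cross(g, d, seed = s)$donor$A02), numeric(1))
  est <- mean(per_seed)
  se <- stats::sd(per_seed) / sqrt(length(per_seed))
  expect_lt(abs(est - 2^-4), 3 * se + 1e-9)
})

test_that("bulks are what the phenotype classes allow", {
  g <- toy_genome(n_snps = 50)
  d <- cross_design(selection_chrom = "A09",
                    selection_pos = g$snp_positions$A09[25],
                    population_size = 300, bulk_size = 20)
  pop <- simulate_cross(g, d, seed = 2)
  bulks <- make_bulks(pop, seed = 5)
  expect_equal(length(bulks$yellow$phenotype), 20)
  expect_true(all(bulks$brown$phenotype == "brown"))

  # forced sample: population of exactly 20 + 20
  idx <- c(which(pop$phenotype == "yellow")[1:20], which(pop$phenotype == "brown")[1:20])
  small <- bsamap:::.subset_population(pop, idx)
  b2 <- make_bulks(small, d, seed = 1)
  expect_identical(b2$yellow$donor$A09,
                   small$donor$A09[small$phenotype == "yellow", , drop = FALSE])
  expect_identical(b2$brown$donor$A09,
                   small$donor$A09[small$phenotype == "brown", , drop = FALSE])

  # insufficient plants of one phenotype -> error naming it
  tiny <- bsamap:::.subset_population(pop, c(which(pop$phenotype == "yellow")[1:25],
                                             which(pop$phenotype == "brown")[1:5]))
  expect_error(make_bulks(tiny, d, seed = 1), "brown")
})

test_that("bulk allele frequencies at the selection locus are exactly 0 and 0.5", {
  g <- toy_genome(n_snps = 80)
  locus <- g$snp_positions$A09[40]
  d <- cross_design(selection_pos = locus, population_size = 400, bulk_size = 20)
  pop <- simulate_cross(g, d, seed = 9)
  bulks <- make_bulks(pop, seed = 4)
  j <- match(locus, g$snp_positions$A09)
  expect_identical(allele_frequencies(bulks$yellow)$A09[j], 0)
  expect_identical(allele_frequencies(bulks$brown)$A09[j], 0.5)
})

test_that("pooled sequencing follows the depth/error model", {
  g <- toy_genome(n_snps = 2000, lengths = c(A09 = 1e6), morgans = c(A09 = 0.5))
  # f = 0, e = 0: no donor reads anywhere
  ad0 <- simulate_pool_depths(list(A09 = 0), g, pool_depth_model(15, 0),
                              seed = 1, sample_name = "p")
  expect_true(all(ad0$p.alt == 0))
  # f = 0.5, e = 0, high depth: mean donor fraction within 0.5 +/- 0.01
  ad5 <- simulate_pool_depths(list(A09 = 0.5), g, pool_depth_model(1000, 0),
                              seed = 2, sample_name = "p")
  frac <- ad5$p.alt / (ad5$p.ref + ad5$p.alt)
  expect_lt(abs(mean(frac) - 0.5), 0.01)
  # zero-depth sites are emitted, not dropped
  adlow <- simulate_pool_depths(list(A09 = 0.2), g, pool_depth_model(0.5, 0.001),
                                seed = 3, sample_name = "p")
  expect_equal(nrow(adlow), length(g$snp_positions$A09))
  expect_gt(sum(adlow$p.ref + adlow$p.alt == 0), 0)
})

test_that("everything is reproducible bit-for-bit given the seed", {
  g <- toy_genome(n_snps = 40)
  d <- cross_design(selection_pos = g$snp_positions$A09[10],
                    population_size = 100, bulk_size = 10)
  p1 <- simulate_cross(g, d, seed = 123)
  p2 <- simulate_cross(g, d, seed = 123)
  expect_identical(p1$donor, p2$donor)
  expect_identical(p1$phenotype, p2$phenotype)
  a1 <- simulate_pool_depths(make_bulks(p1, seed = 1)$brown, g, seed = 8)
  a2 <- simulate_pool_depths(make_bulks(p2, seed = 1)$brown, g, seed = 8)
  expect_identical(a1, a2)
})

test_that("marker screens genotype error-free and respect the chromosome", {
  g <- genome_at(c(1e5, 3e5, 5e5, 7e5), morgans = 0)   # no recombination
  d <- cross_design(selection_pos = 5e5, population_size = 200, bulk_size = 10)
  pop <- simulate_cross(g, d, seed = 21)
  mk <- data.frame(marker = c("at_locus", "linked"), chrom = "A09",
                   start = c(5e5, 3e5), end = c(5e5, 3e5), pos = c(5e5, 3e5))
  scr <- simulate_marker_screen(pop, mk)
  # marker at the locus: zero recombinants with phenotype
  expect_equal(count_recombinants(scr, "at_locus")$k, 0)
  # zero-recombination genome: identical genotype columns
  expect_identical(scr$calls$at_locus, scr$calls$linked)
  bad <- data.frame(marker = "off", chrom = "A02", start = 1e5, end = 1e5)
  expect_error(simulate_marker_screen(pop, bad), "off the selected chromosome")
})

test_that("recombinant counts at 1 cM match the binomial expectation n*r", {
  # single meiosis from a fully heterozygous parent (BC1): E[k] = n * r with
  # r ~ 0.01 at 1 cM, i.e. ~17.4 recombinants among 1,739 plants
  L_bp <- 1e6; G <- 0.5
  locus <- 4e5
  marker <- locus + 0.01 / (G / L_bp)   # 1 cM away under the uniform map
  g <- genome_at(c(locus, marker), length = L_bp, morgans = G)
  d <- cross_design(n_backcrosses = 1, selection_pos = locus,
                    population_size = 1739, bulk_size = 20)
  mk <- data.frame(marker = "m1", chrom = "A09", start = marker, end = marker,
                   pos = marker)
  ks <- vapply(1:200, function(s) {
    scr <- simulate_marker_screen(simulate_cross(g, d, seed = s), mk)
    count_recombinants(scr, "m1")$k
  }, numeric(1))
  expect_lt(abs(mean(ks) - 17.4), 1.0)
  # and the estimated map distance recovers the truth within sampling error
  r_hat <- mean(ks) / 1739
  se_r <- stats::sd(ks / 1739) / sqrt(length(ks))
  expect_lt(abs(kosambi_distance(r_hat) - 1.0), 3 * 100 * se_r + 0.02)
})

test_that("marker screens round-trip through TSV", {
  scr <- published_screen(50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_marker_screen(scr, path)
  back <- read_marker_screen(path)
  expect_equal(back$calls, scr$calls)
  expect_equal(back$markers, scr$markers)
})
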