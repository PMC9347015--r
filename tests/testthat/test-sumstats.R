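test_that("per-site diversity formula matches direct cases", {
  # one heterozygous diploid: n = 2 alleles, j = 1 -> pi = 1
  gm <- genotype_matrix(matrix(1L, 1, 1), "s", "1", 1)
  pm <- pop_map("s", "G")
  expect_equal(nucleotide_diversity(gm, pm, "G")$pi, 1)
  # monomorphic site contributes zero
  gm2 <- genotype_matrix(matrix(c(1L, 0L), 1, 2), "s", c("1", "1"), 1:2)
  expect_equal(nucleotide_diversity(gm2, pop_map("s", "G"), "G",
                                    total_sites = 2)$pi, 0.5)
  # n = 4 alleles, j = 2 -> 2*2*2 / (4*3) = 2/3
  gm3 <- genotype_matrix(matrix(c(1L, 1L), 2, 1), c("a", "b"), "1", 1)
  expect_equal(nucleotide_diversity(gm3, pop_map(c("a", "b"), c("G", "G")),
                                    "G")$pi, 2 / 3)
})

test_that("diversity equals the brute-force pairwise-difference oracle", {
  for (seed in 1:4) {
    gm <- toy_gm(n_samples = 10, n_sites = 50, miss = 0.2, seed = seed)
    pm <- pop_map(gm$sample_ids, rep("G", 10))
    expect_equal(nucleotide_diversity(gm, pm, "G")$pi,
                 oracle_pi(gm, gm$sample_ids), tolerance = 1e-12)
    expect_equal(nucleotide_diversity(gm, pm, "G", total_sites = 500)$pi,
                 oracle_pi(gm, gm$sample_ids, total_sites = 500),
                 tolerance = 1e-12)
  }
})

test_that("Weir-Cockerham F_ST matches the independent transcription", {
  for (seed in 5:8) {
    gm <- toy_gm(n_samples = 14, n_sites = 60, miss = 0.15, seed = seed)
    pm <- toy_popmap(gm)
    a <- group_samples(pm, "G1"); b <- group_samples(pm, "G2")
    expect_equal(fst_weir_cockerham(gm, pm, "G1", "G2")$raw,
                 oracle_wc_fst(gm, a, b), tolerance = 1e-10)
    expect_equal(fst_hudson(gm, pm, "G1", "G2")$raw,
                 oracle_hudson_fst(gm, a, b), tolerance = 1e-10)
  }
})

test_that("F_ST boundary behaviour: no differentiation and fixation", {
  # identical allele counts in both groups -> raw theta <= 0, clipped to 0
  g <- rbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L),
             c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L))
  gm <- genotype_matrix(g, letters[1:4], rep("1", 4), 1:4)
  pm <- pop_map(letters[1:4], c("A", "A", "B", "B"))
  wc <- fst_weir_cockerham(gm, pm, "A", "B")
  expect_lte(wc$raw, 0)
  expect_equal(wc$fst, 0)
  expect_equal(fst_hudson(gm, pm, "A", "B")$fst, 0)
  # fixed difference at every site, large n -> theta -> 1
  g2 <- rbind(matrix(0L, 20, 5), matrix(2L, 20, 5))
  gm2 <- genotype_matrix(g2, sprintf("s%02d", 1:40), rep("1", 5), 1:5)
  pm2 <- pop_map(gm2$sample_ids, rep(c("A", "B"), each = 20))
  expect_gt(fst_weir_cockerham(gm2, pm2, "A", "B")$fst, 0.97)
  expect_equal(fst_hudson(gm2, pm2, "A", "B")$fst, 1)
})

test_that("single-site toy F_ST values are reproduced exactly", {
  # group A: 5 diploids, 2 alt alleles as two hets; group B: mirror image
  g <- rbind(1L, 1L, 0L, 0L, 0L, 1L, 1L, 2L, 2L, 2L)
  gm <- genotype_matrix(matrix(g, 10, 1), sprintf("s%02d", 1:10), "1", 1)
  pm <- pop_map(gm$sample_ids, rep(c("A", "B"), each = 5))
  # frozen values computed with the scalar oracles
  expect_equal(fst_weir_cockerham(gm, pm, "A", "B")$raw,
               oracle_wc_fst(gm, gm$sample_ids[1:5], gm$sample_ids[6:10]),
               tolerance = 1e-12)
  expect_equal(fst_weir_cockerham(gm, pm, "A", "B")$raw, 0.485294117647,
               tolerance = 1e-9)
  # Hudson by hand: p1=0.2, p2=0.8, n=10 alleles each:
  # num = 0.36 - 2*(0.16/9); den = 2*(0.2*0.2 + ... ) -> below
  p1 <- 0.2; p2 <- 0.8
  hand <- ((p1 - p2)^2 - p1 * (1 - p1) / 9 - p2 * (1 - p2) / 9) /
    (p1 * (1 - p2) + p2 * (1 - p1))
  expect_equal(fst_hudson(gm, pm, "A", "B")$raw, hand, tolerance = 1e-12)
})

test_that("ld_r2 handles self, duplicates, independence and degeneracy", {
  gm <- toy_gm(n_samples = 600, n_sites = 4, seed = 10)
  expect_equal(ld_r2(gm, 1, 1), 1)
  gm$geno[, 2] <- gm$geno[, 1] # duplicated column
  expect_equal(ld_r2(gm, 1, 2), 1)
  expect_lt(ld_r2(gm, 3, 4), 0.05) # independent binomial sites, n >= 500
  gm$geno[, 3] <- 1L # zero variance
  expect_true(is.na(ld_r2(gm, 3, 4)))
})

test_that("ld_prune follows the stated greedy rule", {
  # independent sites survive untouched
  gm <- toy_gm(n_samples = 400, n_sites = 8, seed = 21)
  pruned <- ld_prune(gm, window = 8, step = 4, r2_max = 0.2)
  expect_equal(n_sites(pruned), 8)
  # duplicated pair: exactly one of the two removed
  gm2 <- toy_gm(n_samples = 100, n_sites = 5, seed = 22)
  gm2$geno[, 3] <- gm2$geno[, 2]
  pruned2 <- ld_prune(gm2, window = 5, step = 2, r2_max = 0.2)
  expect_equal(n_sites(pruned2), 4)
  expect_equal(sum(c("1:2", "1:3") %in% site_ids(pruned2)), 1)
})

test_that("ld_prune matches a brute-force trace on a correlated triplet", {
  set.seed(30)
  base <- stats::rbinom(200, 2, 0.4)
  flip <- function(x, k) { i <- sample(length(x), k); x[i] <- 2 - x[i]; x }
  g <- cbind(stats::rbinom(200, 2, 0.3), base, flip(base, 12),
             flip(base, 25), stats::rbinom(200, 2, 0.5))
  gm <- genotype_matrix(matrix(as.integer(g), 200), sprintf("s%03d", 1:200),
                        rep("1", 5), 1:5)
  pruned <- ld_prune(gm, window = 5, step = 2, r2_max = 0.2)
  survivors <- oracle_ld_prune_window(gm, 1:5, 0.2)
  expect_equal(site_ids(pruned), site_ids(gm)[survivors])
})

test_that("ld_prune is invariant to sample order", {
  gm <- toy_gm(n_samples = 80, n_sites = 12, seed = 31)
  gm$geno[, 5] <- gm$geno[, 4]
  gm$geno[, 9] <- pmin(2L, gm$geno[, 8] + stats::rbinom(80, 1, 0.05))
  perm <- sample(80)
  gm2 <- genotype_matrix(gm$geno[perm, ], gm$sample_ids[perm],
                         gm$chrom, gm$pos)
  p1 <- ld_prune(gm, window = 6, step = 3, r2_max = 0.2)
  p2 <- ld_prune(gm2, window = 6, step = 3, r2_max = 0.2)
  expect_equal(site_ids(p1), site_ids(p2))
})

test_that("allele-sharing distance matches hand computation", {
  g <- rbind(c(0L, 2L, 1L), c(0L, 2L, 1L), c(2L, 0L, 1L))
  gm <- genotype_matrix(g, c("a", "b", "c"), rep("1", 3), 1:3)
  d <- allele_sharing_distance(gm)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], (2 + 2 + 0) / 3 / 2)
  expect_equal(d["b", "c"], 2 / 3)
  # opposite homozygotes at every site -> 1
  g2 <- rbind(c(0L, 2L), c(2L, 0L))
  gm2 <- genotype_matrix(g2, c("a", "b"), c("1", "1"), 1:2)
  expect_equal(allele_sharing_distance(gm2)["a", "b"], 1)
  # missing overlap errors with the pair named
  g3 <- rbind(c(0L, NA), c(NA, 2L))
  gm3 <- genotype_matrix(g3, c("a", "b"), c("1", "1"), 1:2)
  expect_error(allele_sharing_distance(gm3), "a.*b")
})
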