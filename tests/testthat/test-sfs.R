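test_that("build_sfs with complete data gives integer counts totalling n_sites", {
  gm <- toy_gm(n_samples = 8, n_sites = 40, seed = 1)
  pm <- toy_popmap(gm)
  s <- build_sfs(gm, pm, fold = FALSE)
  expect_equal(s$shape, c(9L, 9L))
  expect_equal(sfs_total(s), 40)
  expect_true(all(s$counts == round(s$counts)))
})

test_that("hypergeometric projection distributes site mass correctly", {
  # one site, n = 4 called alleles with j = 2, projected to 2:
  # P(derived in subsample) = {1/6, 4/6, 1/6}
  gm <- genotype_matrix(matrix(c(1L, 1L), 2, 1), c("a", "b"), "1", 1)
  pm <- pop_map(c("a", "b"), c("G", "G"))
  s <- build_sfs(gm, pm, "G", projection = 2, fold = FALSE)
  expect_equal(as.vector(s$counts), c(1, 4, 1) / 6, tolerance = 1e-12)
})

test_that("projection equals a hypergeometric brute force with missing data", {
  gm <- toy_gm(n_samples = 6, n_sites = 30, miss = 0.25, seed = 3)
  pm <- pop_map(gm$sample_ids, rep("G", 6))
  m <- 6
  s <- build_sfs(gm, pm, "G", projection = m, fold = FALSE)
  # brute force: enumerate all subsets of size m of the called alleles
  expect_brute <- numeric(m + 1)
  for (site in seq_len(n_sites(gm))) {
    al <- integer(0)
    for (i in seq_len(6)) {
      g <- gm$geno[i, site]
      if (!is.na(g)) al <- c(al, switch(g + 1L, c(0L, 0L), c(0L, 1L),
                                        c(1L, 1L)))
    }
    if (length(al) < m) next
    subs <- utils::combn(length(al), m)
    for (k in seq_len(ncol(subs))) {
      d <- sum(al[subs[, k]])
      expect_brute[d + 1] <- expect_brute[d + 1] + 1 / ncol(subs)
    }
  }
  expect_equal(as.vector(s$counts), expect_brute, tolerance = 1e-9)
})

test_that("folding is idempotent and zeroes cells above the fold axis", {
  gm <- toy_gm(n_samples = 5, n_sites = 60, seed = 4)
  pm <- pop_map(gm$sample_ids, rep("G", 5))
  f1 <- build_sfs(gm, pm, "G", fold = TRUE)
  f2 <- fold_sfs(f1)
  expect_equal(f1$counts, f2$counts, tolerance = 1e-12)
  n <- f1$shape - 1
  expect_true(all(f1$counts[(n %/% 2 + 2):(n + 1)] == 0))
  # folded counts equal direct minor-allele tabulation (no missing data)
  j <- colSums(gm$geno)
  minor <- pmin(j, 2 * 5 - j)
  expect_equal(as.vector(f1$counts)[1:(n %/% 2 + 1)],
               as.vector(table(factor(minor, levels = 0:(n %/% 2)))))
})

test_that("marginalization conserves mass and matches hand sums", {
  gm <- toy_gm(n_samples = 9, n_sites = 50, miss = 0.1, seed = 5)
  pm <- pop_map(gm$sample_ids, rep(c("A", "B", "C"), each = 3))
  s <- build_sfs(gm, pm, c("A", "B"), projection = c(4, 4), fold = FALSE)
  expect_equal(marginalize_sfs(s, c("A", "B"))$counts, s$counts,
               tolerance = 1e-12)
  ma <- marginalize_sfs(s, "A")
  expect_equal(as.vector(ma$counts), rowSums(s$counts), tolerance = 1e-9)
  expect_equal(sfs_total(ma), sfs_total(s), tolerance = 1e-9)
  expect_error(marginalize_sfs(s, character(0)), "empty")
})

test_that("projection and marginalization commute", {
  gm <- toy_gm(n_samples = 8, n_sites = 60, miss = 0.15, seed = 6)
  pm <- pop_map(gm$sample_ids, rep(c("A", "B"), each = 4))
  joint <- build_sfs(gm, pm, c("A", "B"), projection = c(5, 5), fold = FALSE)
  a_then <- marginalize_sfs(joint, "A")
  # direct marginal projection restricted to the sites the joint kept
  ncA <- 2 * colSums(!is.na(gm$geno[1:4, , drop = FALSE]))
  ncB <- 2 * colSums(!is.na(gm$geno[5:8, , drop = FALSE]))
  keep <- which(ncA >= 5 & ncB >= 5)
  direct <- build_sfs(subset_sites(gm, keep), pm, "A", projection = 5,
                      fold = FALSE)
  expect_equal(as.vector(a_then$counts), as.vector(direct$counts),
               tolerance = 1e-9)
})

test_that("sparse joint spectra accumulate and serialize losslessly", {
  gm <- toy_gm(n_samples = 12, n_sites = 40, seed = 7)
  pm <- pop_map(gm$sample_ids, rep(c("A", "B", "C", "D"), each = 3))
  s <- build_sfs(gm, pm, fold = TRUE) # 4 populations -> sparse storage
  expect_true(is.list(s$counts))
  expect_equal(sfs_total(s), 40, tolerance = 1e-9)
  path <- tempfile(fileext = ".sfs")
  write_sfs(s, path)
  back <- read_sfs(path)
  expect_equal(back$pop_labels, s$pop_labels)
  expect_equal(back$shape, s$shape)
  o1 <- order(back$counts$cells %*% cumprod(c(1, back$shape[-4])))
  o2 <- order(s$counts$cells %*% cumprod(c(1, s$shape[-4])))
  expect_equal(back$counts$cells[o1, ], s$counts$cells[o2, ])
  expect_equal(back$counts$mass[o1], s$counts$mass[o2], tolerance = 1e-15)
  # dense round-trip too
  d <- build_sfs(gm, pm, c("A", "B"), fold = FALSE)
  p2 <- tempfile(fileext = ".sfs")
  write_sfs(d, p2)
  expect_equal(read_sfs(p2)$counts, d$counts, tolerance = 1e-15)
})

test_that("expected single-population spectrum follows theta over i", {
  expect_equal(expected_sfs_single_pop(2, 1), 1)
  expect_equal(expected_sfs_single_pop(4, 2), c(2, 1, 2 / 3))
  expect_error(expected_sfs_single_pop(1, 1), "n")
})

test_that("simulated mean SFS matches the neutral closed form", {
  N <- 500; mu <- 2e-4; n_dip <- 4; L <- 3000
  model <- single_pop_model(N, n_dip = n_dip, mu = mu, n_loci = L)
  sim <- simulate_genotypes(model, 1234)
  j <- colSums(sim$gm$geno)
  xi <- table(factor(j, levels = 1:(2 * n_dip - 1))) / L
  theta <- 4 * N * mu
  for (i in 1:(2 * n_dip - 1)) {
    se <- sqrt(theta / i / L) * 2 # rough per-class Poisson SE
    expect_lt(abs(xi[[i]] - theta / i), 3 * se + 0.02 * theta / i)
  }
})

test_that("build_sfs is invariant to sample order within groups", {
  gm <- toy_gm(n_samples = 8, n_sites = 30, miss = 0.2, seed = 8)
  pm <- pop_map(gm$sample_ids, rep(c("A", "B"), each = 4))
  s1 <- build_sfs(gm, pm, fold = TRUE)
  perm <- c(4, 2, 3, 1, 8, 6, 5, 7)
  gm2 <- genotype_matrix(gm$geno[perm, ], gm$sample_ids[perm], gm$chrom,
                         gm$pos)
  s2 <- build_sfs(gm2, pm, fold = TRUE)
  expect_equal(s1$counts, s2$counts, tolerance = 1e-12)
})
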