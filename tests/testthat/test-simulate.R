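test_that("pairwise TMRCA and diversity match single-population theory", {
  N <- 800
  model <- single_pop_model(N, n_dip = 1, mu = 1e-4, n_loci = 2500)
  sim <- simulate_genotypes(model, 101)
  # E[T2] = 2N with sd 2N per locus
  se <- 2 * N / sqrt(length(sim$tree_heights))
  expect_lt(abs(mean(sim$tree_heights) - 2 * N), 3 * se)
  # E[pi] = 4 N mu per locus
  d <- nucleotide_diversity(sim$gm, sim$popmap, "A", total_sites = 2500)
  theta <- 4 * N * 1e-4
  expect_lt(abs(d$pi - theta), 0.1 * theta)
})

test_that("Watterson's estimator is unbiased for theta", {
  N <- 600; mu <- 1e-4; n_dip <- 5
  model <- single_pop_model(N, n_dip = n_dip, mu = mu, n_loci = 3000)
  sim <- simulate_genotypes(model, 77)
  harm <- sum(1 / seq_len(2 * n_dip - 1))
  s_per_locus <- n_sites(sim$gm) / 3000
  theta_w <- s_per_locus / harm
  # SE from the empirical spread of per-locus segregating-site counts
  s_counts <- tabulate(match(sim$gm$chrom, unique(sim$gm$chrom)))
  se <- stats::sd(c(s_counts, rep(0, 3000 - length(s_counts)))) /
    sqrt(3000) / harm
  expect_lt(abs(theta_w - 4 * N * mu), 3 * se)
})

test_that("two-population split F_ST matches the closed form", {
  # Hudson 1 - Hw/Hb: E[T2 within] = 2N, E[T2 between] = t + 2N,
  # so the ratio-of-sums estimator converges to t / (t + 2N)
  N <- 500; t <- 500
  model <- split_model(N, t, n_dip = 15, mu = 5e-5, n_loci = 4000)
  sim <- simulate_genotypes(model, 303)
  fst <- fst_hudson(sim$gm, sim$popmap, "A", "B")
  expect_lt(abs(fst$raw - t / (t + 2 * N)), 0.05)
})

test_that("simulator agrees with an independent coalescent implementation", {
  N <- 400; t <- 600; mu <- 1e-4; n_loci <- 1500; n_dip <- 10
  model <- split_model(N, t, n_dip = n_dip, mu = mu, n_loci = n_loci)
  sim <- simulate_genotypes(model, 17)
  pi_a <- nucleotide_diversity(sim$gm, sim$popmap, "A",
                               total_sites = n_loci)$pi
  fst <- fst_hudson(sim$gm, sim$popmap, "A", "B")$raw
  script <- sprintf("
import msprime, numpy as np
dem = msprime.Demography()
dem.add_population(name='A', initial_size=%d)
dem.add_population(name='B', initial_size=%d)
dem.add_population(name='anc', initial_size=%d)
dem.add_population_split(time=%d, derived=['A','B'], ancestral='anc')
pis=[]; num=0.0; den=0.0
reps = msprime.sim_ancestry(samples={'A':%d,'B':%d}, demography=dem,
                            num_replicates=%d, random_seed=11)
for i, ts in enumerate(reps):
    mts = msprime.sim_mutations(ts, rate=%g, random_seed=1000+i,
                                discrete_genome=False)
    n = mts.num_samples
    for v in mts.variants():
        g = v.genotypes
        ja, jb = g[:n//2].sum(), g[n//2:].sum()
        na = nb = n//2
        if ja+jb in (0, na+nb): continue
        p1, p2 = ja/na, jb/nb
        num += (p1-p2)**2 - p1*(1-p1)/(na-1) - p2*(1-p2)/(nb-1)
        den += p1*(1-p2) + p2*(1-p1)
    pis.append(mts.diversity(sample_sets=list(range(n//2)), mode='site'))
print(float(np.mean(pis)), num/den)
", N, N, N, t, n_dip, n_dip, n_loci, mu)
  out <- system2("python", "-", input = script, stdout = TRUE, stderr = FALSE)
  vals <- as.numeric(strsplit(utils::tail(out, 1), " ")[[1]])
  expect_lt(abs(pi_a - vals[1]) / vals[1], 0.1)
  expect_lt(abs(fst - vals[2]), 0.05)
})

test_that("admixture pulses route lineages with probability r", {
  r <- 0.54397
  # A and B anciently diverged and strongly drifted; H founded 1
  # generation ago, huge size so its lineages cannot coalesce first
  model <- demographic_model(
    pop_labels = c("A", "B", "H"),
    sizes = c(A = 300, B = 300, H = 1e7),
    events = data.frame(
      time = c(1, 30000), source = c("H", "B"), dest1 = c("A", "A"),
      dest2 = c("B", NA), p1 = c(r, NA), stringsAsFactors = FALSE),
    mutation_rate = 2e-4, n_sites = 800,
    samples_per_pop = c(A = 15, B = 15, H = 50))
  sim <- simulate_genotypes(model, 41)
  pm <- sim$popmap
  ga <- sim$gm$geno[group_samples(pm, "A"), ]
  gb <- sim$gm$geno[group_samples(pm, "B"), ]
  gh <- sim$gm$geno[group_samples(pm, "H"), ]
  pa <- colMeans(ga) / 2; pb <- colMeans(gb) / 2
  diag_ab <- pa >= 0.99 & pb <= 0.01
  diag_ba <- pb >= 0.99 & pa <= 0.01
  match_a <- c(colMeans(gh[, diag_ab, drop = FALSE]) / 2,
               1 - colMeans(gh[, diag_ba, drop = FALSE]) / 2)
  n_draws <- 100 * length(match_a)
  expect_gt(length(match_a), 30)
  expect_lt(abs(mean(match_a) - r), 3 * sqrt(r * (1 - r) / n_draws) + 0.01)
})

test_that("r = 1 routes every hybrid lineage to the first donor", {
  model <- demographic_model(
    pop_labels = c("A", "B", "H"),
    sizes = c(A = 300, B = 300, H = 1e7),
    events = data.frame(
      time = c(1, 30000), source = c("H", "B"), dest1 = c("A", "A"),
      dest2 = c("B", NA), p1 = c(1, NA), stringsAsFactors = FALSE),
    mutation_rate = 2e-4, n_sites = 400,
    samples_per_pop = c(A = 15, B = 15, H = 20))
  sim <- simulate_genotypes(model, 42)
  pm <- sim$popmap
  fst_ha <- fst_hudson(sim$gm, pm, "H", "A")$raw
  fst_hb <- fst_hudson(sim$gm, pm, "H", "B")$raw
  expect_lt(fst_ha, 0.05)
  expect_gt(fst_hb, 0.5)
})

test_that("simulation is deterministic given the seed", {
  model <- split_model(300, 200, n_dip = 4, mu = 1e-4, n_loci = 300)
  s1 <- simulate_genotypes(model, 99)
  s2 <- simulate_genotypes(model, 99)
  expect_identical(s1$gm$geno, s2$gm$geno)
  expect_identical(s1$tree_heights, s2$tree_heights)
  s3 <- simulate_genotypes(model, 100)
  expect_false(identical(s1$gm$geno, s3$gm$geno))
})

test_that("add_missingness masks at the requested rate, deterministically", {
  gm <- toy_gm(n_samples = 20, n_sites = 500, seed = 3)
  expect_identical(add_missingness(gm, 0, 1), gm)
  masked <- add_missingness(gm, 0.2, 11)
  n_cells <- length(gm$geno)
  frac <- mean(is.na(masked$geno))
  # binomial 99% bounds around 0.2 (slightly widened for dropped sites)
  half <- 2.58 * sqrt(0.2 * 0.8 / n_cells)
  expect_lt(abs(frac - 0.2), half + 0.005)
  expect_identical(add_missingness(gm, 0.2, 11)$geno, masked$geno)
  expect_error(add_missingness(gm, 1, 1), "rate")
})

test_that("model validation rejects broken event structures", {
  expect_error(demographic_model(
    c("A", "B"), c(A = 10, B = 10),
    data.frame(time = numeric(), source = character(), dest1 = character()),
    1e-4, 10, c(A = 1, B = 1)), "root")
  expect_error(demographic_model(
    c("A", "B"), c(A = 10, B = 10),
    data.frame(time = -5, source = "B", dest1 = "A"),
    1e-4, 10, c(A = 1, B = 1)), "positive")
  expect_error(parameter_set(T_hybridization = 500, T_improvement3 = 100),
               "ordering")
  # Table-1 time scaling: domestication event at T/g generations
  m <- build_bayberry_model(parameter_set())
  expect_equal(max(m$events$time), 327)
})
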