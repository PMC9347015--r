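test_that("expected spectrum is normalized and follows 1/i for one population", {
  m <- single_pop_model(500, n_dip = 3, mu = 1e-4, n_loci = 1)
  es <- expected_sfs(m, 20000, 7, mode = "marginal", fold = FALSE)
  p <- as.vector(es$spectra$A$counts)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  theory <- (1 / 1:5) / sum(1 / 1:5)
  expect_lt(max(abs(p[2:6] - theory)), 0.01)
  expect_equal(p[c(1, 7)], c(0, 0)) # monomorphic cells masked
})

test_that("composite log-likelihood matches direct arithmetic and an entropy bound", {
  mk <- function(counts, folded = FALSE)
    new_sfs("A", length(counts), counts, folded = folded)
  # all observed mass in one cell with expected probability 0.5
  obs <- mk(c(0, 10, 0, 0))
  expd <- mk(c(0, 0.5, 0.5, 0))
  expect_equal(composite_loglik(obs, expd), 10 * log(0.5))
  # expected equal to observed proportions maximizes the likelihood
  set.seed(42)
  m <- c(0, 30, 50, 20, 0)
  q <- m / sum(m)
  base <- composite_loglik(mk(m), mk(q))
  expect_equal(base, sum(m[m > 0] * log(q[m > 0])))
  for (i in 1:20) {
    delta <- stats::runif(3, -0.05, 0.05)
    p <- q[2:4] + delta
    p <- p / sum(p)
    expect_lte(composite_loglik(mk(m), mk(c(0, p, 0))), base + 1e-12)
  }
})

test_that("composite log-likelihood equals the per-site oracle", {
  set.seed(9)
  m <- c(0, stats::rpois(5, 20), 0)
  p <- c(0, stats::runif(5), 0)
  p[2:6] <- p[2:6] / sum(p[2:6])
  obs <- new_sfs("A", 7, m)
  expd <- new_sfs("A", 7, p)
  per_site <- sum(unlist(lapply(2:6, function(cell)
    rep(log(p[cell]), m[cell]))))
  expect_equal(composite_loglik(obs, expd), per_site, tolerance = 1e-12)
  # shape mismatch errors
  expect_error(composite_loglik(obs, new_sfs("A", 5, rep(0.25, 5))),
               "match")
})

test_that("a one-parameter fit recovers N and agrees with a grid search", {
  N_true <- 1000; mu <- 2e-4; L <- 2000
  model <- single_pop_model(N_true, n_dip = 5, mu = mu, n_loci = L)
  sim <- simulate_genotypes(model, 555)
  obs <- build_pairwise_sfs(sim$gm, sim$popmap, n_total_loci = L)
  par_table <- data.frame(name = "N", lower = 200, upper = 5000,
                          scale = "log", stringsAsFactors = FALSE)
  builder <- function(nat) single_pop_model(nat[["N"]], n_dip = 5, mu = mu,
                                            n_loci = L)
  settings <- fit_settings(n_sims = 4000, n_starts = 2, maxit = 60,
                           n_cycles = 2)
  fit <- fit_sfs_model(obs, builder, par_table, settings, seed = 3)
  expect_lt(abs(fit$params_hat[["N"]] - N_true) / N_true, 0.2)
  # grid-search oracle over the same bounds confirms the optimum region
  grid <- exp(seq(log(200), log(5000), length.out = 25))
  ll <- vapply(grid, function(N) {
    es <- expected_sfs(builder(c(N = N)), 4000, 12345, mode = "marginal")
    composite_loglik(obs, es) +
      stats::dpois(obs$n_snps, L * mu * es$mean_ttot, log = TRUE)
  }, numeric(1))
  N_grid <- grid[which.max(ll)]
  expect_lt(abs(log(fit$params_hat[["N"]]) - log(N_grid)), log(1.35))
})

test_that("collapsed bounds return the point after one evaluation", {
  model <- single_pop_model(400, n_dip = 3, mu = 1e-4, n_loci = 300)
  sim <- simulate_genotypes(model, 8)
  obs <- build_pairwise_sfs(sim$gm, sim$popmap, n_total_loci = 300)
  par_table <- data.frame(name = "N", lower = 400, upper = 400,
                          scale = "log", stringsAsFactors = FALSE)
  builder <- function(nat) single_pop_model(nat[["N"]], n_dip = 3,
                                            mu = 1e-4, n_loci = 300)
  fit <- fit_sfs_model(obs, builder, par_table,
                       fit_settings(n_sims = 500, n_starts = 3), seed = 2)
  expect_equal(fit$params_hat[["N"]], 400)
  expect_equal(fit$n_evals, 1L)
  expect_true(fit$converged)
})

test_that("two-parameter split fits recover size and time, deterministically", {
  N_true <- 1000; t_true <- 500; mu <- 1e-4; L <- 5000
  model <- split_model(N_true, t_true, n_dip = 8, mu = mu, n_loci = L)
  par_table <- data.frame(name = c("N", "t"), lower = c(200, 50),
                          upper = c(5000, 2500), scale = "log",
                          stringsAsFactors = FALSE)
  builder <- function(nat) split_model(nat[["N"]], nat[["t"]], n_dip = 8,
                                       mu = mu, n_loci = L)
  settings <- fit_settings(n_sims = 4000, n_starts = 3, maxit = 100,
                           n_cycles = 2)
  for (seed in c(21, 22)) {
    sim <- simulate_genotypes(model, seed)
    obs <- build_pairwise_sfs(sim$gm, sim$popmap, n_total_loci = L)
    fit <- fit_sfs_model(obs, builder, par_table, settings, seed = seed)
    expect_lt(abs(fit$params_hat[["N"]] - N_true) / N_true, 0.3)
    expect_lt(abs(fit$params_hat[["t"]] - t_true) / t_true, 0.3)
    refit <- fit_sfs_model(obs, builder, par_table, settings, seed = seed)
    expect_identical(fit$params_hat, refit$params_hat)
  }
})

test_that("model comparison ranks by AIC and prefers the generating model", {
  ps <- parameter_set()
  model <- build_bayberry_model(
    ps, samples_per_pop = c(Wild = 5, PL = 5, FH = 5, DK = 5, BQ = 5, HY = 5),
    n_sites = 30000)
  sim <- simulate_genotypes(model, 71)
  obs <- build_pairwise_sfs(sim$gm, sim$popmap, n_total_loci = 30000)
  spp <- floor(obs$samples / 2)
  settings <- fit_settings(n_sims = 3000, n_starts = 2, maxit = 100,
                           n_cycles = 1)
  pt <- bayberry_par_table()
  cand <- list(
    admixture = list(
      builder = function(nat) build_bayberry_model(
        params_from_gaps(nat, 10), samples_per_pop = spp,
        mutation_rate = 5e-7, n_sites = 30000),
      par_table = pt),
    no_admixture = list(
      builder = function(nat) build_bayberry_model_noadmix(
        params_from_gaps(nat, 10, r = 0), samples_per_pop = spp,
        mutation_rate = 5e-7, n_sites = 30000),
      par_table = pt[pt$name != "r", ]))
  cmp <- compare_models(obs, cand, settings, seed = 5)
  expect_equal(cmp$table$AIC, 2 * cmp$table$k_params - 2 * cmp$table$loglik)
  expect_equal(cmp$best_model, "admixture")
  # identical candidates give identical log-likelihoods (shared seed)
  cand2 <- list(a = cand$admixture, b = cand$admixture)
  cmp2 <- compare_models(obs, cand2,
                         fit_settings(n_sims = 1000, n_starts = 1,
                                      maxit = 30, n_cycles = 1), seed = 5)
  expect_equal(cmp2$table$loglik[1], cmp2$table$loglik[2])
})

test_that("parametric bootstrap produces ordered intervals that cover truth", {
  N_true <- 800; mu <- 2e-4; L <- 1500
  par_table <- data.frame(name = "N", lower = 200, upper = 4000,
                          scale = "log", stringsAsFactors = FALSE)
  builder <- function(nat) single_pop_model(nat[["N"]], n_dip = 4, mu = mu,
                                            n_loci = L)
  settings <- fit_settings(n_sims = 2000, n_starts = 1, maxit = 40,
                           n_cycles = 1)
  sim <- simulate_genotypes(builder(c(N = N_true)), 91)
  obs <- build_pairwise_sfs(sim$gm, sim$popmap, n_total_loci = L)
  fit <- fit_sfs_model(obs, builder, par_table, settings, seed = 4)
  simulate_obs <- function(params, seed) {
    s <- simulate_genotypes(builder(params), seed)
    build_pairwise_sfs(s$gm, s$popmap, n_total_loci = L)
  }
  refit <- function(obs_b, seed)
    fit_sfs_model(obs_b, builder, par_table, settings, seed = seed)
  boot <- parametric_bootstrap(fit, simulate_obs, refit, B = 12, seed = 6)
  expect_true(all(boot$intervals[, "lower"] <= boot$intervals[, "upper"]))
  expect_true(boot$intervals["N", "lower"] <= N_true * 1.2 &&
                boot$intervals["N", "upper"] >= N_true * 0.8)
  expect_error(parametric_bootstrap(fit, simulate_obs, refit, B = 5),
               "B")
})
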