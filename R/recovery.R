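#' Parameter-recovery study under the six-group bayberry model
#'
#' Simulates replicate RAD-like SNP panels under the best-fit parameter
#' values (the [parameter_set()] defaults), refits the model to each by
#' pairwise-SFS composite likelihood, and reports the recovered
#' parameters with their medians across replicates. This is the
#' package's core self-consistency check: with the model, simulator and
#' fit all working, the recovered medians should land inside the
#' published confidence bands.
#'
#' Each replicate simulates `samples_per_pop` diploids per group over
#' `n_sites` unlinked loci (about 5000-6000 SNPs at the default mutation
#' rate). For the fit, the wild and landrace (PL) groups keep all their
#' samples - they carry the deep-time signal - while the drifted
#' cultivar groups are subsampled to `keep` diploids, which halves the
#' coalescent tree size per likelihood evaluation at essentially no cost
#' in information. Sites monomorphic within the retained samples are
#' dropped and the SNP-count anchor is computed on the same sample set.
#'
#' @param n_replicates number of replicate datasets (>= 1).
#' @param seed integer master seed; replicate data and fit seeds derive
#'   from it.
#' @param truth the generating [parameter_set()].
#' @param n_sites unlinked loci per replicate.
#' @param samples_per_pop diploids simulated per group.
#' @param keep named diploid counts retained per group for fitting.
#' @param mutation_rate per-locus mutation rate.
#' @param settings a [fit_settings()].
#' @return a list of class `recovery_study`: `estimates` (one row per
#'   replicate: sizes, r, times in years), `medians`, `truth`, `fits`.
#' @export
parameter_recovery <- function(n_replicates = 5, seed = 1,
                               truth = parameter_set(),
                               n_sites = 125000,
                               samples_per_pop = c(Wild = 10, PL = 10, FH = 10,
                                                   DK = 10, BQ = 10, HY = 10),
                               keep = c(Wild = 10, PL = 10, FH = 5,
                                        DK = 5, BQ = 5, HY = 5),
                               mutation_rate = 5e-7,
                               settings = fit_settings()) {
  model <- build_bayberry_model(truth, samples_per_pop = samples_per_pop,
                                mutation_rate = mutation_rate,
                                n_sites = n_sites)
  fits <- vector("list", n_replicates)
  rows <- vector("list", n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    data_seed <- seed + 1000L * rep_i
    sim <- simulate_genotypes(model, data_seed)
    obs <- recovery_observed(sim, keep, n_sites, data_seed + 1L)
    fit <- fit_bayberry(obs, mutation_rate = mutation_rate,
                        generation_time = truth$generation_time,
                        settings = settings, seed = data_seed + 2L)
    fits[[rep_i]] <- fit
    est <- fit$params_set
    rows[[rep_i]] <- data.frame(
      replicate = rep_i, n_snps = obs$n_snps,
      N_Wild = est$N_Wild, N_PL = est$N_PL, N_FH = est$N_FH,
      N_DK = est$N_DK, N_BQ = est$N_BQ, N_HY = est$N_HY, r = est$r,
      T_hybridization = est$T_hybridization,
      T_improvement3 = est$T_improvement3,
      T_improvement2 = est$T_improvement2,
      T_improvement1 = est$T_improvement1,
      T_domestication = est$T_domestication)
  }
  estimates <- do.call(rbind, rows)
  medians <- vapply(estimates[, -(1:2)], stats::median, numeric(1))
  structure(list(estimates = estimates, medians = medians, truth = truth,
                 fits = fits, seed = seed),
            class = "recovery_study")
}

# subsample for inference, drop sites monomorphic in the subsample, and
# build the observed pairwise spectra with the SNP-count anchor
recovery_observed <- function(sim, keep, n_sites, seed) {
  set.seed(seed)
  groups <- levels(sim$popmap)
  ids <- unlist(lapply(groups, function(g) {
    gs <- group_samples(sim$popmap, g)
    sample(gs, min(keep[[g]], length(gs)))
  }))
  gm <- subset_samples(sim$gm, ids)
  j <- colSums(gm$geno, na.rm = TRUE)
  n <- 2 * colSums(!is.na(gm$geno))
  gm <- subset_sites(gm, which(j > 0 & j < n))
  pm <- pop_map(ids, as.character(sim$popmap[ids]), levels = groups)
  build_pairwise_sfs(gm, pm, n_total_loci = n_sites)
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("recovery_study: %d replicates (seed %d)\n",
              nrow(x$estimates), x$seed))
  cat("medians:\n")
  print(round(x$medians, 3))
  invisible(x)
}
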