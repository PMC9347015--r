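#' Run the full analysis pipeline from one configuration
#'
#' Executes, in order: data acquisition (coalescent simulation under a
#' parameter set, or reading an existing VCF + population map), LD
#' pruning, summary statistics (per-group diversity and pairwise F_ST),
#' pairwise SFS construction, demographic fitting, optional parametric
#' bootstrap, ancestry estimation for each requested K, and a
#' neighbor-joining tree. Every stage writes its outputs into
#' `config$outdir` and is recorded in a manifest (file, stage, md5
#' checksum). A single global `seed` is expanded per stage as
#' `seed + 100 * stage_index`, so stages are independently reproducible.
#' If a manifest from an earlier run is found, stages whose outputs all
#' exist with matching checksums are skipped, which makes a failed run
#' resumable.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   `outdir`; `seed`; either `simulate` (a list of [parameter_set()]
#'   arguments plus optional `samples_per_pop`, `mutation_rate`,
#'   `n_sites`, `missingness`) or `input` (list with `vcf`, `popmap`);
#'   optional `prune` (`window`, `step`, `r2_max`), `stats`
#'   (`total_sites`), `sfs` (`projection`), `fit` (`n_sims`, `n_starts`,
#'   `maxit`, `generation_time`, `admixture`), `bootstrap` (`B`, off
#'   when absent), `ancestry` (`K`, vector), `tree` (`outgroup`), and
#'   `stages` (subset of stage names to run, default all).
#' @return the manifest data frame, invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$outdir)) stop("config$outdir is required")
  if (is.null(config$seed)) stop("config$seed is required")
  if (is.null(config$simulate) && is.null(config$input))
    stop("config needs either a 'simulate' block or an 'input' block")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  all_stages <- c("data", "prune", "stats", "sfs", "fit", "bootstrap",
                  "ancestry", "tree")
  stages <- if (is.null(config$stages)) all_stages else config$stages
  if (is.null(config$bootstrap)) stages <- setdiff(stages, "bootstrap")

  manifest_path <- file.path(outdir, "manifest.json")
  old_manifest <- if (file.exists(manifest_path))
    as.data.frame(jsonlite::read_json(manifest_path, simplifyVector = TRUE))
  else NULL
  manifest <- data.frame(stage = character(), file = character(),
                         md5 = character(), reused = logical(),
                         stringsAsFactors = FALSE)
  log_msg <- function(...) message(sprintf("[bayberry] %s", sprintf(...)))
  stage_done <- function(stage, files) {
    if (is.null(old_manifest)) return(FALSE)
    rec <- old_manifest[old_manifest$stage == stage, , drop = FALSE]
    if (nrow(rec) == 0 || !setequal(rec$file, files)) return(FALSE)
    all(file.exists(rec$file)) &&
      all(unname(tools::md5sum(rec$file)) ==
            rec$md5[match(rec$file, rec$file)])
  }
  record <- function(stage, files, reused = FALSE) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, file = files, md5 = unname(tools::md5sum(files)),
      reused = reused, stringsAsFactors = FALSE))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  }
  stage_seed <- function(stage) seed + 100L * match(stage, all_stages)

  run_stage <- function(stage, files, fn) {
    if (!stage %in% stages) return(invisible(NULL))
    t0 <- Sys.time()
    if (stage_done(stage, files)) {
      log_msg("stage %-9s skipped (outputs up to date)", stage)
      record(stage, files, reused = TRUE)
      return(invisible(NULL))
    }
    withCallingHandlers(
      tryCatch(fn(), error = function(e)
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)),
      message = function(m) invokeRestart("muffleMessage"))
    record(stage, files)
    log_msg("stage %-9s done in %.1fs", stage,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  vcf_path <- file.path(outdir, "data.vcf")
  popmap_path <- file.path(outdir, "data.popmap")
  sim_cfg <- config$simulate
  run_stage("data", c(vcf_path, popmap_path), function() {
    if (!is.null(sim_cfg)) {
      ps_args <- sim_cfg[intersect(names(sim_cfg), names(formals(parameter_set)))]
      ps <- do.call(parameter_set, ps_args)
      spp <- unlist(sim_cfg$samples_per_pop %||%
                      c(Wild = 10, PL = 10, FH = 10, DK = 10, BQ = 10, HY = 10))
      model <- build_bayberry_model(
        ps, samples_per_pop = spp,
        mutation_rate = sim_cfg$mutation_rate %||% 5e-7,
        n_sites = sim_cfg$n_sites %||% 150000)
      sim <- simulate_genotypes(model, stage_seed("data"))
      gm <- sim$gm
      if (!is.null(sim_cfg$missingness) && sim_cfg$missingness > 0)
        gm <- add_missingness(gm, sim_cfg$missingness, stage_seed("data") + 1L)
      write_vcf(gm, vcf_path)
      write_popmap(sim$popmap, popmap_path)
      # loci count travels in a side file so the fit can anchor its scale
      writeLines(as.character(model$n_sites),
                 file.path(outdir, "data.n_loci"))
    } else {
      file.copy(config$input$vcf, vcf_path, overwrite = TRUE)
      file.copy(config$input$popmap, popmap_path, overwrite = TRUE)
    }
  })
  gm <- read_vcf(vcf_path)
  popmap <- read_popmap(popmap_path, gm)
  n_loci_file <- file.path(outdir, "data.n_loci")
  n_total_loci <- if (file.exists(n_loci_file))
    as.integer(readLines(n_loci_file)) else NULL

  pruned_path <- file.path(outdir, "pruned.vcf")
  run_stage("prune", pruned_path, function() {
    pr <- config$prune %||% list()
    pruned <- ld_prune(gm, window = pr$window %||% 50,
                       step = pr$step %||% 10, r2_max = pr$r2_max %||% 0.2)
    write_vcf(pruned, pruned_path)
  })
  gm_pruned <- if (file.exists(pruned_path)) read_vcf(pruned_path) else gm

  stats_path <- file.path(outdir, "stats.tsv")
  run_stage("stats", stats_path, function() {
    pi <- diversity_by_group(gm, popmap,
                             total_sites = config$stats$total_sites %||%
                               n_total_loci)
    fm <- fst_matrix(gm, popmap)
    rows <- data.frame(statistic = paste0("pi_", names(pi)),
                       value = unname(pi))
    pr <- which(upper.tri(fm$fst), arr.ind = TRUE)
    rows <- rbind(rows, data.frame(
      statistic = paste0("fst_", rownames(fm$fst)[pr[, 1]], "_",
                         colnames(fm$fst)[pr[, 2]]),
      value = fm$fst[pr]))
    utils::write.table(rows, stats_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  sfs_dir <- file.path(outdir, "sfs")
  sfs_files <- function() file.path(sfs_dir, paste0(
    apply(t(utils::combn(levels(popmap), 2)), 1, paste, collapse = "_"),
    ".sfs"))
  run_stage("sfs", sfs_files(), function() {
    dir.create(sfs_dir, showWarnings = FALSE)
    obs <- build_pairwise_sfs(gm, popmap,
                              projection = config$sfs$projection,
                              n_total_loci = n_total_loci)
    for (nm in names(obs$spectra))
      write_sfs(obs$spectra[[nm]], file.path(sfs_dir, paste0(nm, ".sfs")))
  })

  fit_path <- file.path(outdir, "fit.json")
  run_stage("fit", fit_path, function() {
    fc <- config$fit %||% list()
    obs <- build_pairwise_sfs(gm, popmap,
                              projection = config$sfs$projection,
                              n_total_loci = n_total_loci)
    fit <- fit_bayberry(
      obs, mutation_rate = (config$simulate$mutation_rate %||% 5e-7),
      generation_time = fc$generation_time %||% 10,
      admixture = fc$admixture %||% TRUE,
      settings = fit_settings(n_sims = fc$n_sims %||% 10000,
                              n_starts = fc$n_starts %||% 5,
                              maxit = fc$maxit %||% 150),
      seed = stage_seed("fit"))
    out <- c(as.list(fit$params_set[
      c("N_Wild", "N_PL", "N_FH", "N_DK", "N_BQ", "N_HY", "r",
        "T_hybridization", "T_improvement3", "T_improvement2",
        "T_improvement1", "T_domestication", "generation_time")]),
      list(loglik = fit$loglik, n_evals = fit$n_evals,
           converged = fit$converged, seed = fit$seed,
           settings = unclass(fit$settings)))
    jsonlite::write_json(out, fit_path, auto_unbox = TRUE, digits = NA)
  })

  boot_path <- file.path(outdir, "bootstrap.json")
  run_stage("bootstrap", boot_path, function() {
    bc <- config$bootstrap
    fc <- config$fit %||% list()
    fitj <- jsonlite::read_json(fit_path, simplifyVector = TRUE)
    settings <- fit_settings(n_sims = fc$n_sims %||% 10000,
                             n_starts = bc$n_starts %||% 2,
                             maxit = fc$maxit %||% 150)
    g_time <- fc$generation_time %||% 10
    mu <- config$simulate$mutation_rate %||% 5e-7
    spp <- c(table(as.character(popmap)))
    fit0 <- list(params_hat = NULL)
    ps_hat <- parameter_set(
      N_Wild = fitj$N_Wild, N_PL = fitj$N_PL, N_FH = fitj$N_FH,
      N_DK = fitj$N_DK, N_BQ = fitj$N_BQ, N_HY = fitj$N_HY, r = fitj$r,
      T_hybridization = fitj$T_hybridization,
      T_improvement3 = fitj$T_improvement3,
      T_improvement2 = fitj$T_improvement2,
      T_improvement1 = fitj$T_improvement1,
      T_domestication = fitj$T_domestication, generation_time = g_time)
    simulate_obs <- function(params, seed_b) {
      model <- build_bayberry_model(ps_hat, samples_per_pop = spp,
                                    mutation_rate = mu,
                                    n_sites = n_total_loci %||% 20000)
      sim <- simulate_genotypes(model, seed_b)
      build_pairwise_sfs(sim$gm, sim$popmap, n_total_loci = model$n_sites)
    }
    refit <- function(obs_b, seed_b)
      fit_bayberry(obs_b, mutation_rate = mu, generation_time = g_time,
                   settings = settings, seed = seed_b)
    fit0$params_hat <- unlist(fitj[bayberry_par_table()$name[1:7]])
    boot <- parametric_bootstrap(fit0, simulate_obs, refit,
                                 B = bc$B %||% 50,
                                 seed = stage_seed("bootstrap"))
    jsonlite::write_json(list(intervals = as.data.frame(boot$intervals),
                              n_used = boot$n_used),
                         boot_path, auto_unbox = TRUE, digits = NA)
  })

  anc_cfg <- config$ancestry %||% list(K = c(2, 3, 4))
  anc_files <- as.vector(vapply(anc_cfg$K, function(k)
    file.path(outdir, sprintf("ancestry.%d.%s", k, c("Q", "P"))),
    character(2)))
  run_stage("ancestry", anc_files, function() {
    for (k in anc_cfg$K) {
      res <- fit_admixture(gm_pruned, k,
                           n_starts = anc_cfg$n_starts %||% 8,
                           seed = stage_seed("ancestry") + k)
      write_ancestry(res, file.path(outdir, "ancestry"))
    }
  })

  tree_path <- file.path(outdir, "tree.nwk")
  run_stage("tree", tree_path, function() {
    tree <- genotype_nj_tree(gm_pruned, outgroup = config$tree$outgroup)
    write_newick(tree, tree_path)
  })

  log_msg("pipeline complete: %d artifacts in %s",
          nrow(manifest), outdir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
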