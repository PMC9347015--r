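#' Expected site-frequency spectrum of a demographic model
#'
#' Simulates `n_sims` independent coalescent trees under `model` and
#' accumulates, for every branch, its length into the frequency class of
#' its descendant set. Because under infinite sites a SNP lands on a
#' branch with probability proportional to its length, the normalized
#' accumulated mass is the conditional probability of each polymorphic
#' SFS cell in the low-mutation limit; working with branch lengths
#' instead of literal mutation drops removes all mutation-sampling noise
#' from the estimate. Cells never hit receive a floor of
#' `eps = 0.1 / n_sims` before renormalization so the composite
#' likelihood is never `-Inf`. Deterministic given `seed`.
#'
#' @param model a [demographic_model()].
#' @param n_sims number of simulated trees (>= 100).
#' @param seed integer seed.
#' @param mode `"pairwise"` (folded 2-D spectra for every population
#'   pair; the inference default), `"marginal"` (per-population folded
#'   1-D spectra) or `"joint"` (sparse joint spectrum, unnormalized
#'   branch mass).
#' @param fold fold the spectra (default `TRUE`)?
#' @param eps probability floor for unobserved cells.
#' @return a list of class `expected_sfs`: `spectra` (named list of `sfs`
#'   objects holding cell probabilities; for `"joint"`, one sparse
#'   `sfs`), `mean_ttot`, `mean_tmrca` (generations), `n_sims`, `mode`.
#' @export
expected_sfs <- function(model, n_sims, seed, mode = c("pairwise", "marginal",
                                                       "joint"),
                         fold = TRUE, eps = NULL) {
  mode <- match.arg(mode)
  if (n_sims < 100) stop("n_sims must be >= 100")
  if (is.null(eps)) eps <- 0.1 / n_sims
  set.seed(seed)
  spp <- model$samples_per_pop
  keep <- spp > 0
  labels <- model$pop_labels[keep]
  samp <- 2L * spp[keep]
  res <- cpp_expected_sfs(model$sizes[keep], samp, event_matrix(model),
                          as.integer(n_sims), mode == "joint")
  if (res$mean_ttot <= 0)
    stop("no polymorphic mass simulated; increase n_sims or theta")
  spectra <- list()
  if (mode == "pairwise") {
    if (length(labels) < 2) stop("pairwise mode needs >= 2 sampled populations")
    qi <- 0
    for (a in seq_along(labels)[-length(labels)])
      for (b in seq((a + 1), length(labels))) {
        qi <- qi + 1
        m <- res$pairwise[[qi]]
        s <- new_sfs(labels[c(a, b)], dim(m), m)
        if (fold) s <- fold_sfs(s)
        spectra[[paste(labels[a], labels[b], sep = "_")]] <-
          normalize_expected(s, eps)
      }
  } else if (mode == "marginal") {
    for (p in seq_along(labels)) {
      v <- res$marginal[[p]]
      s <- new_sfs(labels[p], length(v), v)
      if (fold) s <- fold_sfs(s)
      spectra[[labels[p]]] <- normalize_expected(s, eps)
    }
  } else {
    keys <- res$joint$key
    strides <- cumprod(c(1, samp[-length(samp)] + 1))
    cells <- matrix(0L, nrow = length(keys), ncol = length(labels))
    rem <- keys
    for (p in rev(seq_along(labels))) {
      cells[, p] <- as.integer(rem %/% strides[p])
      rem <- rem %% strides[p]
    }
    s <- accumulate_sfs(labels, samp + 1L, cells, res$joint$mass)
    if (fold) s <- fold_sfs(s)
    spectra[["joint"]] <- s
  }
  structure(list(spectra = spectra, mean_ttot = res$mean_ttot,
                 mean_tmrca = res$mean_tmrca, n_sims = n_sims, mode = mode,
                 fold = fold),
            class = "expected_sfs")
}

# mask monomorphic boundary cells, apply the floor, normalize to probs
normalize_expected <- function(sfs, eps) {
  stopifnot(!is_sparse_sfs(sfs))
  a <- sfs$counts
  mask <- polymorphic_mask(sfs)
  a[!mask] <- 0
  a[mask & a <= 0] <- eps
  a <- a / sum(a)
  out <- new_sfs(sfs$pop_labels, sfs$shape, a, folded = sfs$folded,
                 monomorphic_included = FALSE)
  out
}

# TRUE for cells that correspond to sites polymorphic within these pops;
# for folded spectra the all-ancestral cell (and, unfolded, the all-derived
# cell) are the monomorphic boundaries. Cells unreachable after folding are
# also masked.
polymorphic_mask <- function(sfs) {
  shape <- sfs$shape
  cells <- arrayInd(seq_len(prod(shape)), shape) - 1L
  d <- rowSums(cells)
  nmax <- sum(shape - 1L)
  mask <- d > 0 & d < nmax
  if (sfs$folded) {
    canon <- fold_cells(cells, shape)
    mask <- mask & rowSums(abs(canon - cells)) == 0
  }
  array(mask, dim = shape)
}

#' Multinomial composite log-likelihood of an observed spectrum
#'
#' `sum_i m_i log p_i` over polymorphic cells, where `m_i` are observed
#' counts and `p_i` expected cell probabilities. Cells with `m_i = 0`
#' contribute nothing; expected zeros under positive observations are
#' impossible by construction because [expected_sfs()] floors them.
#'
#' @param observed an `sfs` of observed counts, or a `pairwise_sfs`.
#' @param expected the matching normalized `sfs` from [expected_sfs()],
#'   or the `expected_sfs` object itself when `observed` is a
#'   `pairwise_sfs` (log-likelihoods are then summed over pairs).
#' @return composite log-likelihood (scalar).
#' @export
composite_loglik <- function(observed, expected) {
  if (inherits(observed, "pairwise_sfs")) {
    stopifnot(inherits(expected, "expected_sfs"))
    return(sum(vapply(names(observed$spectra), function(nm) {
      if (is.null(expected$spectra[[nm]]))
        stop("expected spectrum missing for pair ", nm)
      composite_loglik(observed$spectra[[nm]], expected$spectra[[nm]])
    }, numeric(1))))
  }
  stopifnot(inherits(observed, "sfs"), inherits(expected, "sfs"))
  if (!identical(observed$pop_labels, expected$pop_labels) ||
      !identical(observed$shape, expected$shape) ||
      !identical(observed$folded, expected$folded))
    stop("observed and expected spectra do not match in labels/shape/folding")
  if (is_sparse_sfs(observed) || is_sparse_sfs(expected))
    stop("composite_loglik requires dense spectra (<= 3 populations)")
  mask <- polymorphic_mask(expected)
  m <- observed$counts[mask]
  p <- expected$counts[mask]
  if (any(m > 0 & p <= 0)) stop("expected probability zero at observed cell")
  sum(m[m > 0] * log(p[m > 0]))
}

#' Optimiser settings for SFS fits
#'
#' The fit explores with `n_starts` Nelder-Mead starts on a cheap
#' low-fidelity surface (`warm_sims` trees per evaluation), then refines
#' the incumbent with `n_cycles` full-fidelity Nelder-Mead runs, each
#' under a fresh common-random-number seed. Refreshing the seed between
#' cycles stops the optimizer from climbing into wrinkles of one
#' particular simulation noise realization, which otherwise displaces
#' the optimum along weakly-identified ridges.
#'
#' @param n_sims coalescent trees per likelihood evaluation (refinement).
#' @param n_starts number of warm-up Nelder-Mead starts.
#' @param maxit function-evaluation cap per Nelder-Mead run.
#' @param n_cycles seed-refreshed refinement runs.
#' @param warm_sims trees per evaluation during warm-up (default
#'   `max(2000, n_sims / 4)`).
#' @param start_step,cycle_step initial simplex edge lengths (transformed
#'   coordinates) for warm-up and refinement.
#' @param reltol relative convergence tolerance.
#' @return a list of class `fit_settings`.
#' @export
fit_settings <- function(n_sims = 10000, n_starts = 5, maxit = 200,
                         n_cycles = 4, warm_sims = NULL,
                         start_step = 0.7, cycle_step = 0.3,
                         reltol = 1e-8) {
  if (is.null(warm_sims)) warm_sims <- max(2000, round(n_sims / 4))
  structure(list(n_sims = n_sims, n_starts = n_starts, maxit = maxit,
                 n_cycles = n_cycles, warm_sims = warm_sims,
                 start_step = start_step, cycle_step = cycle_step,
                 reltol = reltol), class = "fit_settings")
}

# bounded transform: y in R -> natural in [lo, hi]
# log scale interpolates geometrically, linear arithmetically
y_to_nat <- function(y, lo, hi, scale) {
  s <- 1 / (1 + exp(-y))
  ifelse(scale == "log", exp(log(lo) + (log(hi) - log(lo)) * s),
         lo + (hi - lo) * s)
}

#' Nelder-Mead minimisation with an explicit initial simplex scale
#'
#' Standard downhill-simplex search with the dimension-adaptive
#' reflection/expansion/contraction coefficients of Gao & Han, which
#' behave better than the classic constants in 10+ dimensions. Unlike
#' `stats::optim`, the initial simplex step is set explicitly rather
#' than proportionally to the starting values, which matters when the
#' search runs in transformed coordinates centred near zero.
#'
#' @param fn objective to minimise.
#' @param y0 numeric start vector.
#' @param step initial simplex edge length per coordinate.
#' @param maxit maximum function evaluations.
#' @param reltol stop when the simplex value spread falls below
#'   `reltol * (|best| + reltol)`.
#' @return list with `par`, `value`, `evals`.
#' @export
nelder_mead <- function(fn, y0, step = 0.4, maxit = 500, reltol = 1e-8) {
  n <- length(y0)
  alpha <- 1; beta <- 1 + 2 / n; gamma <- 0.75 - 1 / (2 * n); delta <- 1 - 1 / n
  simplex <- matrix(rep(y0, n + 1), nrow = n + 1, byrow = TRUE)
  for (i in seq_len(n)) simplex[i + 1, i] <- simplex[i + 1, i] + step
  vals <- apply(simplex, 1, fn)
  evals <- n + 1
  while (evals < maxit) {
    ord <- order(vals)
    simplex <- simplex[ord, , drop = FALSE]
    vals <- vals[ord]
    if (abs(vals[n + 1] - vals[1]) <=
        reltol * (abs(vals[1]) + reltol)) break
    centroid <- colMeans(simplex[1:n, , drop = FALSE])
    xr <- centroid + alpha * (centroid - simplex[n + 1, ])
    fr <- fn(xr); evals <- evals + 1
    if (fr < vals[1]) {
      xe <- centroid + beta * (xr - centroid)
      fe <- fn(xe); evals <- evals + 1
      if (fe < fr) { simplex[n + 1, ] <- xe; vals[n + 1] <- fe }
      else { simplex[n + 1, ] <- xr; vals[n + 1] <- fr }
    } else if (fr < vals[n]) {
      simplex[n + 1, ] <- xr; vals[n + 1] <- fr
    } else {
      if (fr < vals[n + 1]) { # outside contraction
        xc <- centroid + gamma * (xr - centroid)
        fc <- fn(xc); evals <- evals + 1
        if (fc <= fr) { simplex[n + 1, ] <- xc; vals[n + 1] <- fc }
        else {
          for (i in 2:(n + 1)) {
            simplex[i, ] <- simplex[1, ] + delta * (simplex[i, ] - simplex[1, ])
            vals[i] <- fn(simplex[i, ])
          }
          evals <- evals + n
        }
      } else { # inside contraction
        xc <- centroid - gamma * (xr - centroid)
        fc <- fn(xc); evals <- evals + 1
        if (fc < vals[n + 1]) { simplex[n + 1, ] <- xc; vals[n + 1] <- fc }
        else {
          for (i in 2:(n + 1)) {
            simplex[i, ] <- simplex[1, ] + delta * (simplex[i, ] - simplex[1, ])
            vals[i] <- fn(simplex[i, ])
          }
          evals <- evals + n
        }
      }
    }
  }
  ord <- order(vals)
  list(par = simplex[ord[1], ], value = vals[ord[1]], evals = evals)
}

#' Fit a demographic model to observed pairwise spectra
#'
#' Maximizes the composite log-likelihood (sum over all pairwise folded
#' spectra, plus, when the observed object knows its total locus count,
#' a Poisson term on the observed SNP count that anchors the absolute
#' scale of the model) over a bounded parameter box, using multi-start
#' Nelder-Mead on sigmoid-transformed coordinates. Common random numbers
#' (the same simulation seed at every evaluation) make the stochastic
#' likelihood surface deterministic so the optimizer can descend it.
#'
#' @param observed a `pairwise_sfs` from [build_pairwise_sfs()].
#' @param builder `function(par)` mapping a named natural parameter
#'   vector to a [demographic_model()] whose sampled population sizes
#'   match `observed`. Time-ordering constraints should be enforced by
#'   parameterizing gaps inside the builder, as [fit_bayberry()] does.
#' @param par_table data frame with columns `name`, `lower`, `upper`,
#'   `scale` (`"log"` or `"linear"`) and optionally `init` (natural
#'   scale; defaults to the box midpoint for the first start).
#' @param settings a [fit_settings()].
#' @param seed integer seed (start draws and the common-random-number
#'   simulation seed both derive from it).
#' @return a list of class `demog_fit`: `params_hat` (named natural
#'   vector), `loglik`, `n_evals`, `converged`, `seed`, `settings`.
#' @export
fit_sfs_model <- function(observed, builder, par_table,
                          settings = fit_settings(), seed = 1) {
  stopifnot(inherits(observed, "pairwise_sfs"))
  k <- nrow(par_table)
  if (any(par_table$lower > par_table$upper) ||
      any(!is.finite(par_table$lower)) || any(!is.finite(par_table$upper)))
    stop("parameter bounds must be finite with lower <= upper")
  n_evals <- 0L
  nat_of <- function(y) {
    v <- y_to_nat(y, par_table$lower, par_table$upper, par_table$scale)
    names(v) <- par_table$name
    v
  }
  fold <- observed$spectra[[1]]$folded
  sfs_mode <- if (nrow(observed$pairs) == 0) "marginal" else "pairwise"
  mkobjective <- function(crn, n_sims) function(y) {
    n_evals <<- n_evals + 1L
    nat <- nat_of(y)
    model <- builder(nat)
    es <- expected_sfs(model, n_sims, crn, mode = sfs_mode, fold = fold)
    ll <- composite_loglik(observed, es)
    if (!is.null(observed$n_total_loci)) {
      lambda <- observed$n_total_loci * model$mutation_rate * es$mean_ttot
      ll <- ll + stats::dpois(observed$n_snps, lambda, log = TRUE)
    }
    if (!is.finite(ll)) ll <- -1e18
    -ll
  }
  set.seed(seed)
  crns <- sample.int(2^30, settings$n_cycles + 1)
  point_box <- par_table$upper - par_table$lower == 0
  if (all(point_box)) { # degenerate box: a single admissible point
    nat <- par_table$lower
    names(nat) <- par_table$name
    ll <- -mkobjective(crns[1], settings$n_sims)(rep(0, k))
    return(structure(list(params_hat = nat, loglik = ll, n_evals = n_evals,
                          converged = TRUE, seed = seed, settings = settings,
                          par = rep(0, k), par_table = par_table),
                     class = "demog_fit"))
  }
  starts <- matrix(stats::runif(settings$n_starts * k, -2, 2),
                   nrow = settings$n_starts)
  if (!is.null(par_table$init)) {
    s <- pmin(pmax((par_table$init - par_table$lower) /
                     (par_table$upper - par_table$lower), 1e-6), 1 - 1e-6)
    if (any(par_table$scale == "log")) {
      lg <- par_table$scale == "log"
      s[lg] <- pmin(pmax((log(par_table$init[lg]) - log(par_table$lower[lg])) /
                           (log(par_table$upper[lg]) - log(par_table$lower[lg])),
                         1e-6), 1 - 1e-6)
    }
    starts[1, ] <- log(s / (1 - s))
  } else {
    starts[1, ] <- 0
  }
  # warm-up: multi-start exploration on the cheap surface
  warm_obj <- mkobjective(crns[1], settings$warm_sims)
  init_value <- warm_obj(starts[1, ])
  best <- NULL
  for (st in seq_len(settings$n_starts)) {
    fit <- nelder_mead(warm_obj, starts[st, ], step = settings$start_step,
                       maxit = settings$maxit, reltol = settings$reltol)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  conv <- best$value < init_value + 1e-9 # improved over the first init
  # refinement: full fidelity, fresh common-random-number seed per cycle
  # (values are not comparable across cycles; the last cycle is reported)
  for (cyc in seq_len(settings$n_cycles)) {
    obj <- mkobjective(crns[cyc + 1], settings$n_sims)
    best <- nelder_mead(obj, best$par, step = settings$cycle_step,
                        maxit = settings$maxit, reltol = settings$reltol)
  }
  params_hat <- nat_of(best$par)
  params_hat[point_box] <- par_table$lower[point_box]
  structure(list(params_hat = params_hat, loglik = -best$value,
                 n_evals = n_evals, converged = conv, seed = seed,
                 settings = settings, par = best$par,
                 par_table = par_table),
            class = "demog_fit")
}

#' @export
print.demog_fit <- function(x, ...) {
  cat(sprintf("demog_fit: loglik %.2f after %d evaluations (%s)\n",
              x$loglik, x$n_evals,
              if (x$converged) "converged" else "not converged"))
  print(round(x$params_hat, 4))
  invisible(x)
}

#' Default parameter box for the six-group bayberry fit
#'
#' Bounds are the published 95 percent confidence bands widened fourfold
#' (fully user-configurable); times are parameterized as the five
#' positive gaps between consecutive events, in years, so the event
#' ordering holds by construction.
#'
#' @return a `par_table` data frame for [fit_sfs_model()].
#' @export
bayberry_par_table <- function() {
  data.frame(
    name = c("N_Wild", "N_PL", "N_FH", "N_DK", "N_BQ", "N_HY", "r",
             "G_hyb", "G_imp3", "G_imp2", "G_imp1", "G_dom"),
    lower = c(810, 97, 2.5, 2.5, 2.5, 2.5, 0.05, 2.5, 1, 1, 10, 50),
    upper = c(47120, 8976, 412, 356, 288, 488, 0.95, 720, 2160, 6920,
              11200, 34280),
    scale = c(rep("log", 6), "linear", rep("log", 5)),
    stringsAsFactors = FALSE)
}

#' Convert a gap-parameterized vector to a parameter set
#'
#' The fit optimizes event times as the five positive gaps between
#' consecutive events (`G_hyb`, `G_imp3`, `G_imp2`, `G_imp1`, `G_dom`,
#' years), which guarantees the time ordering by construction. This
#' helper turns such a named vector (plus sizes and, optionally, `r`)
#' back into a [parameter_set()] with absolute times; useful when
#' assembling custom model candidates for [compare_models()].
#'
#' @param nat named vector with the six sizes, the five gaps, and `r`
#'   unless supplied separately.
#' @param generation_time years per generation.
#' @param r admixture proportion override (e.g. `0` for the
#'   no-admixture variant whose parameter vector has no `r`).
#' @return a [parameter_set()].
#' @export
params_from_gaps <- function(nat, generation_time, r = NULL) {
  tt <- cumsum(nat[c("G_hyb", "G_imp3", "G_imp2", "G_imp1", "G_dom")])
  parameter_set(N_Wild = nat[["N_Wild"]], N_PL = nat[["N_PL"]],
                N_FH = nat[["N_FH"]], N_DK = nat[["N_DK"]],
                N_BQ = nat[["N_BQ"]], N_HY = nat[["N_HY"]],
                r = if (is.null(r)) nat[["r"]] else r,
                T_hybridization = tt[[1]], T_improvement3 = tt[[2]],
                T_improvement2 = tt[[3]], T_improvement1 = tt[[4]],
                T_domestication = tt[[5]],
                generation_time = generation_time)
}

#' Fit the six-group bayberry model
#'
#' Convenience wrapper around [fit_sfs_model()] for the bayberry model
#' (with or without the BQ-into-HY admixture pulse). Returns the fitted
#' parameters both as the raw optimizer vector and as a
#' [parameter_set()] with absolute times in years.
#'
#' @param observed a `pairwise_sfs` built over the six groups, with
#'   `n_total_loci` set when the locus total is known.
#' @param mutation_rate per-locus mutation rate used by the model.
#' @param n_sites locus count passed to the candidate models (only the
#'   SNP-count anchor uses the absolute number; defaults to the observed
#'   total when known).
#' @param generation_time years per generation.
#' @param admixture fit the admixture pulse (`TRUE`) or the plain
#'   divergence variant (`FALSE`)?
#' @param par_table bounds, defaulting to [bayberry_par_table()].
#' @param settings a [fit_settings()].
#' @param seed integer seed.
#' @return a `demog_fit` with an extra element `params_set`
#'   (a [parameter_set()]).
#' @export
fit_bayberry <- function(observed, mutation_rate = 5e-7, n_sites = NULL,
                         generation_time = 10, admixture = TRUE,
                         par_table = bayberry_par_table(),
                         settings = fit_settings(), seed = 1) {
  stopifnot(inherits(observed, "pairwise_sfs"))
  if (is.null(n_sites)) n_sites <- observed$n_total_loci
  if (is.null(n_sites)) n_sites <- observed$n_snps
  spp <- floor(observed$samples / 2)
  if (!admixture) par_table <- par_table[par_table$name != "r", ]
  build <- if (admixture) build_bayberry_model else build_bayberry_model_noadmix
  builder <- function(nat) {
    ps <- params_from_gaps(nat, generation_time,
                           r = if (admixture) NULL else 0)
    build(ps, samples_per_pop = spp, mutation_rate = mutation_rate,
          n_sites = n_sites)
  }
  fit <- fit_sfs_model(observed, builder, par_table, settings, seed)
  fit$params_set <- params_from_gaps(fit$params_hat, generation_time,
                                     r = if (admixture) NULL else 0)
  fit$admixture <- admixture
  fit
}

#' Compare candidate demographic models by AIC
#'
#' Fits every candidate and ranks them by `AIC = 2k - 2 logL` (composite
#' log-likelihood); ties within `1e-6` are broken in favour of fewer
#' parameters. Individual fit failures are recorded and the comparison
#' proceeds over the successes.
#'
#' @param observed a `pairwise_sfs`.
#' @param candidates named list; each element is a list with `builder`
#'   and `par_table` as for [fit_sfs_model()].
#' @param settings a [fit_settings()].
#' @param seed integer seed (shared across candidates so they see the
#'   same random numbers).
#' @return a list of class `model_comparison`: `table` (name, loglik,
#'   k_params, AIC), `fits`, `best_model`.
#' @export
compare_models <- function(observed, candidates, settings = fit_settings(),
                           seed = 1) {
  stopifnot(length(candidates) >= 2, !is.null(names(candidates)))
  fits <- lapply(names(candidates), function(nm) {
    tryCatch(fit_sfs_model(observed, candidates[[nm]]$builder,
                           candidates[[nm]]$par_table, settings, seed),
             error = function(e) e)
  })
  names(fits) <- names(candidates)
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) stop("all candidate fits failed")
  tab <- data.frame(
    name = names(candidates)[ok],
    loglik = vapply(fits[ok], function(f) f$loglik, numeric(1)),
    k_params = vapply(candidates[ok], function(cc) nrow(cc$par_table),
                      numeric(1)),
    stringsAsFactors = FALSE)
  tab$AIC <- 2 * tab$k_params - 2 * tab$loglik
  ord <- order(tab$AIC, tab$k_params)
  tab <- tab[ord, ]
  best <- tab$name[1]
  if (nrow(tab) > 1 && abs(tab$AIC[1] - tab$AIC[2]) < 1e-6 &&
      tab$k_params[2] < tab$k_params[1]) best <- tab$name[2]
  structure(list(table = tab, fits = fits, best_model = best,
                 failed = names(candidates)[!ok]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("best model:", x$best_model, "\n")
  invisible(x)
}

#' Parametric-bootstrap confidence intervals
#'
#' Simulates `B` datasets under the fitted parameters, refits each, and
#' returns per-parameter 2.5/97.5 percentile intervals. Individual refit
#' failures are dropped with a warning; more than 20 percent failures is
#' an error.
#'
#' @param fit a `demog_fit`.
#' @param simulate_obs `function(params_hat, seed)` returning a new
#'   observed `pairwise_sfs` simulated under the fitted parameters.
#' @param refit `function(observed, seed)` returning a new `demog_fit`.
#' @param B number of bootstrap replicates (>= 10).
#' @param seed integer seed.
#' @return a list of class `bootstrap_result`: `estimates` (B x k
#'   matrix) and `intervals` (k x 2, `lower <= upper`).
#' @export
parametric_bootstrap <- function(fit, simulate_obs, refit, B = 50, seed = 1) {
  if (B < 10) stop("B must be >= 10")
  est <- vector("list", B)
  for (b in seq_len(B)) {
    sub_seed <- seed * 1000L + b
    est[[b]] <- tryCatch({
      obs_b <- simulate_obs(fit$params_hat, sub_seed)
      refit(obs_b, sub_seed)$params_hat
    }, error = function(e) NULL)
  }
  failed <- vapply(est, is.null, logical(1))
  if (mean(failed) > 0.2)
    stop(sprintf("%d of %d bootstrap refits failed", sum(failed), B))
  if (any(failed))
    warning(sum(failed), " bootstrap refit(s) failed and were dropped")
  m <- do.call(rbind, est[!failed])
  ints <- t(apply(m, 2, stats::quantile, probs = c(0.025, 0.975),
                  names = FALSE))
  colnames(ints) <- c("lower", "upper")
  structure(list(estimates = m, intervals = ints, B = B,
                 n_used = sum(!failed)),
            class = "bootstrap_result")
}
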