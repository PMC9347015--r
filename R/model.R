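#' Demographic parameter set for the six-group bayberry model
#'
#' Holds the free parameters of the six-population domestication model:
#' per-group diploid effective sizes, the admixture proportion `r` of the
#' BQ donor into the hybrid (HY) group, and five event times in years.
#' Times must be ordered
#' `T_hybridization <= T_improvement3 <= T_improvement2 <= T_improvement1
#' <= T_domestication`. `generation_time` (years per generation) converts
#' years to the generations used internally; the default is 10 years,
#' a mid-range value for a long-lived grafted fruit tree.
#'
#' The argument defaults are the best-fit point estimates of the model
#' (sizes 4526, 1504, 25, 16, 20, 37; r 0.54397; times 60, 100, 240,
#' 1890, 3270 years), so `parameter_set()` with no arguments reproduces
#' the study conditions the simulator emulates.
#'
#' @param N_Wild,N_PL,N_FH,N_DK,N_BQ,N_HY diploid effective sizes (>= 1).
#' @param r admixture proportion of the BQ donor into HY, in `[0, 1]`.
#' @param T_hybridization,T_improvement3,T_improvement2,T_improvement1,T_domestication
#'   event times in years before present (> 0, non-decreasing in this order).
#' @param generation_time years per generation used for conversion.
#' @return an object of class `parameter_set` (a named list).
#' @export
parameter_set <- function(N_Wild = 4526, N_PL = 1504, N_FH = 25, N_DK = 16,
                          N_BQ = 20, N_HY = 37, r = 0.54397,
                          T_hybridization = 60, T_improvement3 = 100,
                          T_improvement2 = 240, T_improvement1 = 1890,
                          T_domestication = 3270, generation_time = 10) {
  ps <- list(N_Wild = N_Wild, N_PL = N_PL, N_FH = N_FH, N_DK = N_DK,
             N_BQ = N_BQ, N_HY = N_HY, r = r,
             T_hybridization = T_hybridization,
             T_improvement3 = T_improvement3,
             T_improvement2 = T_improvement2,
             T_improvement1 = T_improvement1,
             T_domestication = T_domestication,
             generation_time = generation_time)
  sizes <- unlist(ps[1:6])
  if (any(sizes < 1)) stop("effective sizes must be >= 1")
  if (r < 0 || r > 1) stop("admixture proportion r must lie in [0, 1]")
  tt <- unlist(ps[8:12])
  if (tt[1] <= 0) stop("event times must be positive")
  if (any(diff(tt) < 0))
    stop("time ordering violated: need T_hybridization <= T_improvement3 <= ",
         "T_improvement2 <= T_improvement1 <= T_domestication")
  if (generation_time <= 0) stop("generation_time must be positive")
  structure(ps, class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("parameter_set (six-group bayberry model)\n")
  cat(sprintf("  N: Wild %g, PL %g, FH %g, DK %g, BQ %g, HY %g\n",
              x$N_Wild, x$N_PL, x$N_FH, x$N_DK, x$N_BQ, x$N_HY))
  cat(sprintf("  r = %g\n", x$r))
  cat(sprintf("  T (years): hyb %g, imp3 %g, imp2 %g, imp1 %g, dom %g",
              x$T_hybridization, x$T_improvement3, x$T_improvement2,
              x$T_improvement1, x$T_domestication),
      sprintf(" (generation time %g y)\n", x$generation_time))
  invisible(x)
}

#' General multi-population demographic model
#'
#' Populations with constant diploid sizes plus a time-ordered list
#' (backward in time, generations) of events. Each event moves all
#' lineages of `source` into `dest1` (a divergence, viewed backward), or,
#' when `dest2` is given, routes each lineage independently to `dest1`
#' with probability `p1` and to `dest2` otherwise (an admixture pulse
#' founding `source`). `new_size`, when given, resets the size of `dest1`
#' at the event, which is how ancestral branch sizes are expressed.
#' After applying all events exactly one population must remain, so every
#' sampled lineage has a single root.
#'
#' @param pop_labels character vector of population labels.
#' @param sizes named or parallel numeric vector of diploid sizes.
#' @param events data frame with columns `time` (generations, > 0,
#'   non-decreasing), `source`, `dest1`, `dest2` (label or `NA`), `p1`
#'   (probability, `NA` means 1) and optionally `new_size`.
#' @param mutation_rate mutation rate per locus per generation.
#' @param n_sites number of unlinked loci to simulate.
#' @param samples_per_pop named integer vector of diploid sample counts.
#' @return an object of class `demographic_model`.
#' @export
demographic_model <- function(pop_labels, sizes, events, mutation_rate,
                              n_sites, samples_per_pop) {
  pop_labels <- as.character(pop_labels)
  if (anyDuplicated(pop_labels)) stop("duplicate population labels")
  if (!is.null(names(sizes))) sizes <- sizes[pop_labels]
  sizes <- as.numeric(sizes)
  if (length(sizes) != length(pop_labels) || anyNA(sizes))
    stop("sizes must cover every population label")
  if (any(sizes < 1)) stop("all population sizes must be >= 1")
  events <- as.data.frame(events)
  if (is.null(events$new_size)) events$new_size <- rep(NA_real_, nrow(events))
  if (is.null(events$dest2)) events$dest2 <- rep(NA_character_, nrow(events))
  if (is.null(events$p1)) events$p1 <- rep(NA_real_, nrow(events))
  ev <- events[order(events$time), , drop = FALSE]
  if (nrow(ev) && any(ev$time <= 0)) stop("event times must be strictly positive")
  if (nrow(ev) && any(ev$p1 < 0 | ev$p1 > 1, na.rm = TRUE))
    stop("admixture proportions must lie in [0, 1]")
  # backward-in-time reachability: after all events one population remains
  active <- pop_labels
  for (i in seq_len(nrow(ev))) {
    src <- ev$source[i]; d1 <- ev$dest1[i]; d2 <- ev$dest2[i]
    if (!src %in% active) stop("event source not active at its time: ", src)
    if (!d1 %in% active) stop("event destination not active: ", d1)
    if (!is.na(d2) && !d2 %in% active) stop("event destination not active: ", d2)
    if (src == d1) stop("event source equals destination: ", src)
    active <- setdiff(active, src)
  }
  if (length(active) != 1)
    stop("model has no single root: populations left after all events: ",
         paste(active, collapse = ", "))
  if (mutation_rate < 0) stop("mutation_rate must be non-negative")
  if (n_sites < 1) stop("n_sites must be >= 1")
  spp <- samples_per_pop
  if (is.null(names(spp))) names(spp) <- pop_labels
  spp <- spp[pop_labels]
  spp[is.na(spp)] <- 0L
  structure(list(pop_labels = pop_labels, sizes = sizes, events = ev,
                 mutation_rate = mutation_rate, n_sites = as.integer(n_sites),
                 samples_per_pop = as.integer(spp), root = active),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("demographic_model: %d populations (%s), %d events, mu=%g, %d loci\n",
              length(x$pop_labels), paste(x$pop_labels, collapse = ", "),
              nrow(x$events), x$mutation_rate, x$n_sites))
  invisible(x)
}

# events matrix for the C++ backend: 0-based population indices
event_matrix <- function(model) {
  ev <- model$events
  if (nrow(ev) == 0)
    return(matrix(numeric(), ncol = 6))
  cbind(ev$time,
        match(ev$source, model$pop_labels) - 1,
        match(ev$dest1, model$pop_labels) - 1,
        ifelse(is.na(ev$dest2), NA_real_, match(ev$dest2, model$pop_labels) - 1),
        ev$p1,
        ev$new_size)
}

#' Build the six-group bayberry domestication model
#'
#' Encodes, backward in time: at `T_hybridization` the hybrid group HY is
#' resolved as an admixture pulse of BQ (with probability `r`) and FH
#' (`1 - r`); at `T_improvement3` BQ merges into DK (their common recent
#' cultivar, kept at `N_DK`); at `T_improvement2` that ancestor merges
#' into FH and the cultivar stem is resized to `N_PL` (a landrace-scale
#' cultivated population, since elite cultivars had not yet been singled
#' out); at `T_improvement1` the cultivar ancestor merges into PL; and at
#' `T_domestication` PL merges into the wild group. Years are converted
#' to generations with `ps$generation_time`.
#'
#' @param ps a [parameter_set()].
#' @param samples_per_pop named diploid sample counts (Wild, PL, FH, DK,
#'   BQ, HY).
#' @param mutation_rate mutation rate per locus per generation. The
#'   default `5e-7` corresponds to a 50 bp RAD tag at 1e-8 per site.
#' @param n_sites number of unlinked loci.
#' @return a [demographic_model()].
#' @export
build_bayberry_model <- function(ps,
                                 samples_per_pop = c(Wild = 10, PL = 10, FH = 10,
                                                     DK = 10, BQ = 10, HY = 10),
                                 mutation_rate = 5e-7, n_sites = 150000) {
  stopifnot(inherits(ps, "parameter_set"))
  g <- ps$generation_time
  events <- data.frame(
    time = c(ps$T_hybridization, ps$T_improvement3, ps$T_improvement2,
             ps$T_improvement1, ps$T_domestication) / g,
    source = c("HY", "BQ", "DK", "FH", "PL"),
    dest1 = c("BQ", "DK", "FH", "PL", "Wild"),
    dest2 = c("FH", NA, NA, NA, NA),
    p1 = c(ps$r, NA, NA, NA, NA),
    new_size = c(NA, NA, ps$N_PL, NA, NA),
    stringsAsFactors = FALSE)
  demographic_model(
    pop_labels = c("Wild", "PL", "FH", "DK", "BQ", "HY"),
    sizes = c(Wild = ps$N_Wild, PL = ps$N_PL, FH = ps$N_FH,
              DK = ps$N_DK, BQ = ps$N_BQ, HY = ps$N_HY),
    events = events, mutation_rate = mutation_rate, n_sites = n_sites,
    samples_per_pop = samples_per_pop)
}

#' Variant of the bayberry model without the hybridization pulse
#'
#' Identical to [build_bayberry_model()] except that HY is treated as a
#' plain divergence from FH at `T_hybridization` (no admixture, no `r`).
#' Used as the alternative candidate in model comparison.
#'
#' @inheritParams build_bayberry_model
#' @return a [demographic_model()].
#' @export
build_bayberry_model_noadmix <- function(ps,
                                         samples_per_pop = c(Wild = 10, PL = 10,
                                                             FH = 10, DK = 10,
                                                             BQ = 10, HY = 10),
                                         mutation_rate = 5e-7, n_sites = 150000) {
  stopifnot(inherits(ps, "parameter_set"))
  g <- ps$generation_time
  events <- data.frame(
    time = c(ps$T_hybridization, ps$T_improvement3, ps$T_improvement2,
             ps$T_improvement1, ps$T_domestication) / g,
    source = c("HY", "BQ", "DK", "FH", "PL"),
    dest1 = c("FH", "DK", "FH", "PL", "Wild"),
    dest2 = NA_character_,
    p1 = NA_real_,
    new_size = c(NA, NA, ps$N_PL, NA, NA),
    stringsAsFactors = FALSE)
  demographic_model(
    pop_labels = c("Wild", "PL", "FH", "DK", "BQ", "HY"),
    sizes = c(Wild = ps$N_Wild, PL = ps$N_PL, FH = ps$N_FH,
              DK = ps$N_DK, BQ = ps$N_BQ, HY = ps$N_HY),
    events = events, mutation_rate = mutation_rate, n_sites = n_sites,
    samples_per_pop = samples_per_pop)
}
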