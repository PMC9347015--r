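#' Simulate diploid genotypes under a demographic model
#'
#' Runs the structured coalescent backward in time for `model$n_sites`
#' independent loci (free recombination between loci, none within):
#' within-population pairs coalesce at rate `1/(2N)` per pair and
#' generation, divergence events move all lineages of the derived
#' population into the ancestral one, and admixture events route each
#' lineage to the first donor with probability `r`. Mutations fall on
#' branches as Poisson with rate `mutation_rate` per generation under the
#' infinite-sites model; every mutation yields one biallelic SNP column
#' (ALT = derived). Haplotypes are paired into diploids at random within
#' each population. Deterministic given `seed`.
#'
#' @param model a [demographic_model()].
#' @param seed integer seed.
#' @return a list of class `sim_result` with elements `gm`
#'   (a [genotype_matrix()] of the segregating sites), `popmap`
#'   (a [pop_map()]), `tree_heights` (per-locus TMRCA in generations),
#'   `n_loci` (loci simulated, i.e. the monomorphic + polymorphic total),
#'   `mean_ttot` (mean total tree length in generations) and `seed`.
#' @export
simulate_genotypes <- function(model, seed) {
  stopifnot(inherits(model, "demographic_model"))
  set.seed(seed)
  spp <- model$samples_per_pop
  keep <- spp > 0
  res <- cpp_sim_snps(model$sizes[keep], 2L * spp[keep],
                      event_matrix(model), model$n_sites,
                      model$mutation_rate)
  labels <- model$pop_labels[keep]
  n_hap_pop <- 2L * spp[keep]
  H <- res$haplotypes
  # random pairing of haplotypes into diploids within each population
  offset <- 0L
  rows_a <- integer(0); rows_b <- integer(0)
  sample_ids <- character(0); groups <- character(0)
  for (p in seq_along(labels)) {
    perm <- sample(n_hap_pop[p])
    ra <- offset + perm[seq(1, n_hap_pop[p], by = 2)]
    rb <- offset + perm[seq(2, n_hap_pop[p], by = 2)]
    rows_a <- c(rows_a, ra); rows_b <- c(rows_b, rb)
    sample_ids <- c(sample_ids, sprintf("%s_%02d", labels[p], seq_len(spp[keep][p])))
    groups <- c(groups, rep(labels[p], spp[keep][p]))
    offset <- offset + n_hap_pop[p]
  }
  n_snps <- ncol(H)
  if (n_snps > 0) {
    geno <- H[rows_a, , drop = FALSE] + H[rows_b, , drop = FALSE]
    # one pseudo-chromosome per locus keeps SNPs of a locus adjacent
    ord <- order(res$locus, seq_len(n_snps))
    geno <- geno[, ord, drop = FALSE]
    loc <- res$locus[ord]
    pos <- stats::ave(seq_along(loc), loc, FUN = seq_along)
    chrom <- sprintf("L%06d", loc + 1L)
  } else {
    geno <- matrix(integer(), nrow = length(rows_a), ncol = 0)
    chrom <- character(); pos <- integer()
  }
  gm <- genotype_matrix(geno, sample_ids, chrom, as.integer(pos))
  pm <- pop_map(sample_ids, groups, levels = labels)
  structure(list(gm = gm, popmap = pm, tree_heights = res$tmrca,
                 n_loci = model$n_sites, mean_ttot = res$mean_ttot,
                 seed = seed),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d SNPs from %d loci, %d samples (seed %d)\n",
              n_sites(x$gm), x$n_loci, n_samples(x$gm), x$seed))
  invisible(x)
}

#' Mask genotypes at random to emulate RAD-seq sparsity
#'
#' Each called genotype is independently set to missing with probability
#' `rate`; sites left with no called genotype are dropped. Deterministic
#' given `seed`.
#'
#' @param gm a [genotype_matrix()].
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return a [genotype_matrix()].
#' @export
add_missingness <- function(gm, rate, seed) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  set.seed(seed)
  if (rate == 0 || n_sites(gm) == 0) return(gm)
  g <- gm$geno
  mask <- matrix(stats::runif(length(g)) < rate, nrow = nrow(g))
  g[mask] <- NA_integer_
  keep <- colSums(!is.na(g)) > 0
  genotype_matrix(g[, keep, drop = FALSE], gm$sample_ids,
                  gm$chrom[keep], gm$pos[keep], gm$ref[keep], gm$alt[keep])
}
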