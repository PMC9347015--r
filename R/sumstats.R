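#' Per-site nucleotide diversity of one group
#'
#' For each site with `n >= 2` called alleles in the group and `j`
#' alternate alleles, the per-site diversity is the unbiased pairwise
#' heterozygosity `2 j (n - j) / (n (n - 1))`. The reported value is the
#' sum over sites divided by `total_sites` when given (SNPs plus
#' monomorphic sites, giving per-total-site diversity on the scale
#' usually printed for RAD data), otherwise by the number of usable SNP
#' sites (flagged `variant_only`).
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [pop_map()] covering `gm`.
#' @param group group label.
#' @param total_sites optional total number of sites (variant +
#'   monomorphic) for the denominator.
#' @return a list of class `diversity_result`: `pi`, `n_sites_used`,
#'   `variant_only`.
#' @export
nucleotide_diversity <- function(gm, popmap, group, total_sites = NULL) {
  validate_popmap(popmap, gm)
  ids <- group_samples(popmap, group)
  g <- gm$geno[ids, , drop = FALSE]
  called <- colSums(!is.na(g))
  n <- 2 * called
  j <- colSums(g, na.rm = TRUE)
  use <- n >= 2
  if (!any(use))
    stop("group ", group, " has no site with at least two called alleles")
  pi_site <- 2 * j[use] * (n[use] - j[use]) / (n[use] * (n[use] - 1))
  denom <- if (is.null(total_sites)) sum(use) else total_sites
  structure(list(pi = sum(pi_site) / denom, n_sites_used = sum(use),
                 variant_only = is.null(total_sites)),
            class = "diversity_result")
}

#' Nucleotide diversity for every group
#'
#' @inheritParams nucleotide_diversity
#' @return named numeric vector of per-group diversity.
#' @export
diversity_by_group <- function(gm, popmap, total_sites = NULL) {
  vapply(levels(popmap), function(gr)
    nucleotide_diversity(gm, popmap, gr, total_sites)$pi, numeric(1))
}

# per-site allele counts for two groups; rows: n1, j1, n2, j2 (alleles)
pair_counts <- function(gm, popmap, group_a, group_b) {
  validate_popmap(popmap, gm)
  ga <- gm$geno[group_samples(popmap, group_a), , drop = FALSE]
  gb <- gm$geno[group_samples(popmap, group_b), , drop = FALSE]
  list(n1 = 2 * colSums(!is.na(ga)), j1 = colSums(ga, na.rm = TRUE),
       n2 = 2 * colSums(!is.na(gb)), j2 = colSums(gb, na.rm = TRUE),
       het1 = colSums(ga == 1L, na.rm = TRUE), ca = colSums(!is.na(ga)),
       het2 = colSums(gb == 1L, na.rm = TRUE), cb = colSums(!is.na(gb)))
}

#' Weir & Cockerham (1984) F_ST between two groups
#'
#' The theta-hat estimator from the per-site variance components `a`
#' (among populations), `b` (among individuals within populations) and
#' `c` (within individuals), combined across sites as a ratio of sums
#' `sum(a) / sum(a + b + c)`. Sites monomorphic across both groups, or
#' without at least one called diploid genotype in each group, are
#' excluded. The raw estimate can be slightly negative in the absence of
#' differentiation; the reported `fst` is clipped to `[0, 1]` with the
#' raw value retained.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [pop_map()].
#' @param group_a,group_b group labels.
#' @return list of class `fst_result`: `fst` (clipped), `raw`,
#'   `n_sites_used`.
#' @export
fst_weir_cockerham <- function(gm, popmap, group_a, group_b) {
  pc <- pair_counts(gm, popmap, group_a, group_b)
  # diploid sample counts and allele frequencies per site
  n1 <- pc$ca; n2 <- pc$cb
  use <- n1 >= 1 & n2 >= 1
  p1 <- ifelse(use, pc$j1 / (2 * n1), NA)
  p2 <- ifelse(use, pc$j2 / (2 * n2), NA)
  poly <- use & (pc$j1 + pc$j2 > 0) & (pc$j1 + pc$j2 < pc$n1 + pc$n2)
  if (!any(poly)) stop("no shared polymorphic site between ",
                       group_a, " and ", group_b)
  n1 <- n1[poly]; n2 <- n2[poly]; p1 <- p1[poly]; p2 <- p2[poly]
  h1 <- pc$het1[poly] / n1; h2 <- pc$het2[poly] / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  ok <- is.finite(a) & is.finite(b) & is.finite(cc)
  raw <- sum(a[ok]) / sum((a + b + cc)[ok])
  structure(list(fst = min(max(raw, 0), 1), raw = raw, n_sites_used = sum(ok)),
            class = "fst_result")
}

#' Hudson (1992) F_ST between two groups
#'
#' The ratio-of-sums estimator `1 - Hw/Hb` with the sample-size-corrected
#' per-site components of Bhatia et al.: numerator
#' `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and denominator
#' `p1(1-p2) + p2(1-p1)` with `n` counted in alleles. Convenient for
#' simulator validation because a two-population split of time `t` with
#' size `N` gives the closed form `F_ST ~ 1 - exp(-t/(2N))`.
#'
#' @inheritParams fst_weir_cockerham
#' @return list of class `fst_result`: `fst` (clipped), `raw`,
#'   `n_sites_used`.
#' @export
fst_hudson <- function(gm, popmap, group_a, group_b) {
  pc <- pair_counts(gm, popmap, group_a, group_b)
  use <- pc$n1 >= 2 & pc$n2 >= 2
  poly <- use & (pc$j1 + pc$j2 > 0) & (pc$j1 + pc$j2 < pc$n1 + pc$n2)
  if (!any(poly)) stop("no shared polymorphic site between ",
                       group_a, " and ", group_b)
  n1 <- pc$n1[poly]; n2 <- pc$n2[poly]
  p1 <- pc$j1[poly] / n1; p2 <- pc$j2[poly] / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  raw <- sum(num) / sum(den)
  structure(list(fst = min(max(raw, 0), 1), raw = raw, n_sites_used = sum(poly)),
            class = "fst_result")
}

#' Pairwise F_ST matrix over all groups
#'
#' @inheritParams fst_weir_cockerham
#' @param estimator `"wc"` (Weir-Cockerham, the reporting default) or
#'   `"hudson"`.
#' @return list of class `fst_matrix`: `fst` (clipped, symmetric, zero
#'   diagonal) and `raw`.
#' @export
fst_matrix <- function(gm, popmap, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  f <- if (estimator == "wc") fst_weir_cockerham else fst_hudson
  gr <- levels(popmap)
  k <- length(gr)
  m <- matrix(0, k, k, dimnames = list(gr, gr))
  raw <- m
  for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
    est <- f(gm, popmap, gr[a], gr[b])
    m[a, b] <- m[b, a] <- est$fst
    raw[a, b] <- raw[b, a] <- est$raw
  }
  structure(list(fst = m, raw = raw, estimator = estimator),
            class = "fst_matrix")
}

#' Composite LD between two sites
#'
#' Squared Pearson correlation of 0/1/2 genotype codes over
#' jointly-called samples. Returns `NA` (not computable) when fewer than
#' two jointly-called samples remain or either site has zero variance
#' among them.
#'
#' @param gm a [genotype_matrix()].
#' @param site_i,site_j site indices (columns).
#' @return `r^2` in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(gm, site_i, site_j) {
  x <- gm$geno[, site_i]; y <- gm$geno[, site_j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# minor allele frequency per site (over called alleles)
site_maf <- function(gm) {
  n <- 2 * colSums(!is.na(gm$geno))
  j <- colSums(gm$geno, na.rm = TRUE)
  pmin(j / n, 1 - j / n)
}

#' Sliding-window greedy LD pruning
#'
#' Within each window of `window` SNPs (advancing by `step`), while any
#' surviving pair has `r^2 > r2_max` the pair with the largest `r^2` is
#' taken (ties: earliest pair in site order) and its member with the
#' lower minor-allele frequency is removed (ties: the later site).
#' Windows never span chromosomes. Deterministic and invariant to sample
#' order.
#'
#' @param gm a [genotype_matrix()].
#' @param window window size in SNPs (>= 2).
#' @param step step size in SNPs.
#' @param r2_max removal threshold, in `(0, 1)`.
#' @return the pruned [genotype_matrix()].
#' @export
ld_prune <- function(gm, window = 50, step = 10, r2_max = 0.2) {
  if (window < 2) stop("window must be >= 2")
  if (step < 1) stop("step must be >= 1")
  if (r2_max <= 0 || r2_max >= 1) stop("r2_max must lie in (0, 1)")
  maf <- site_maf(gm)
  alive <- rep(TRUE, n_sites(gm))
  for (block in split(seq_len(n_sites(gm)),
                      factor(gm$chrom, levels = unique(gm$chrom)))) {
    starts <- seq(1, max(length(block) - window + 1, 1), by = step)
    for (st in starts) {
      win <- block[st:min(st + window - 1, length(block))]
      repeat {
        idx <- win[alive[win]]
        if (length(idx) < 2) break
        r2 <- suppressWarnings(
          stats::cor(gm$geno[, idx, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        diag(r2) <- 0
        r2[lower.tri(r2)] <- 0
        if (all(is.na(r2) | r2 <= r2_max)) break
        top <- which(r2 == max(r2, na.rm = TRUE), arr.ind = TRUE)[1, ]
        i <- idx[top[1]]; j <- idx[top[2]]
        drop <- if (maf[i] < maf[j]) i
          else if (maf[j] < maf[i]) j
          else max(i, j)
        alive[drop] <- FALSE
      }
    }
  }
  subset_sites(gm, which(alive))
}

#' Allele-sharing distance between all sample pairs
#'
#' `d(a, b)` is the mean over jointly-called sites of `|g_a - g_b| / 2`;
#' 0 for identical genotypes, 1 for opposite homozygotes at every site.
#'
#' @param gm a [genotype_matrix()] with at least two samples.
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
allele_sharing_distance <- function(gm) {
  n <- n_samples(gm)
  if (n < 2) stop("need at least two samples")
  d <- matrix(0, n, n, dimnames = list(gm$sample_ids, gm$sample_ids))
  g <- gm$geno
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
    ok <- !is.na(g[a, ]) & !is.na(g[b, ])
    if (!any(ok)) stop("samples ", gm$sample_ids[a], " and ",
                       gm$sample_ids[b], " share no called site")
    d[a, b] <- d[b, a] <- mean(abs(g[a, ok] - g[b, ok])) / 2
  }
  d
}
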