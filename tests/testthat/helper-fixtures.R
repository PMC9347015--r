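# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written as plain scalar loops, independent of
# the vectorised package implementations they check.

# small genotype matrix with optional missingness, seeded
toy_gm <- function(n_samples = 6, n_sites = 20, miss = 0, seed = 1,
                   maf_min = 0.1) {
  set.seed(seed)
  repeat {
    p <- stats::runif(n_sites, maf_min, 1 - maf_min)
    g <- vapply(p, function(pp) stats::rbinom(n_samples, 2, pp),
                integer(n_samples))
    g <- matrix(as.integer(g), nrow = n_samples)
    if (miss > 0) g[stats::runif(length(g)) < miss] <- NA_integer_
    ok <- colSums(!is.na(g)) > 0
    if (all(ok)) break
  }
  genotype_matrix(g, sprintf("s%02d", seq_len(n_samples)),
                  rep("1", n_sites), seq_len(n_sites))
}

toy_popmap <- function(gm, k = 2) {
  n <- n_samples(gm)
  groups <- rep(paste0("G", seq_len(k)), length.out = n)
  pop_map(gm$sample_ids, sort(groups))
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# ------------------------------------------------------------------
# brute-force nucleotide diversity: mean over all allele pairs per site
oracle_pi <- function(gm, ids, total_sites = NULL) {
  g <- gm$geno[ids, , drop = FALSE]
  tot <- 0
  used <- 0
  for (s in seq_len(ncol(g))) {
    # expand genotypes to alleles: 0 -> (0,0), 1 -> (0,1), 2 -> (1,1)
    alleles <- integer(0)
    for (i in seq_len(nrow(g))) {
      if (!is.na(g[i, s]))
        alleles <- c(alleles, switch(g[i, s] + 1L, c(0L, 0L), c(0L, 1L),
                                     c(1L, 1L)))
    }
    n <- length(alleles)
    if (n < 2) next
    used <- used + 1
    diff <- 0; pairs <- 0
    for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
      pairs <- pairs + 1
      if (alleles[a] != alleles[b]) diff <- diff + 1
    }
    tot <- tot + diff / pairs
  }
  tot / if (is.null(total_sites)) used else total_sites
}

# ------------------------------------------------------------------
# scalar transcription of the Weir & Cockerham (1984) theta-hat for two
# populations, per-site a/b/c components combined as ratio of sums
oracle_wc_fst <- function(gm, ids_a, ids_b) {
  ga <- gm$geno[ids_a, , drop = FALSE]
  gb <- gm$geno[ids_b, , drop = FALSE]
  num <- 0; den <- 0
  r <- 2
  for (s in seq_len(ncol(ga))) {
    xa <- ga[, s][!is.na(ga[, s])]
    xb <- gb[, s][!is.na(gb[, s])]
    n1 <- length(xa); n2 <- length(xb)
    if (n1 < 1 || n2 < 1) next
    j1 <- sum(xa); j2 <- sum(xb)
    if (j1 + j2 == 0 || j1 + j2 == 2 * (n1 + n2)) next
    p1 <- j1 / (2 * n1); p2 <- j2 / (2 * n2)
    h1 <- mean(xa == 1); h2 <- mean(xb == 1)
    nbar <- (n1 + n2) / 2
    if (nbar <= 1) next
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (!is.finite(a + b + cc)) next
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# scalar Hudson estimator (Bhatia ratio of sums)
oracle_hudson_fst <- function(gm, ids_a, ids_b) {
  ga <- gm$geno[ids_a, , drop = FALSE]
  gb <- gm$geno[ids_b, , drop = FALSE]
  num <- 0; den <- 0
  for (s in seq_len(ncol(ga))) {
    xa <- ga[, s][!is.na(ga[, s])]
    xb <- gb[, s][!is.na(gb[, s])]
    n1 <- 2 * length(xa); n2 <- 2 * length(xb)
    if (n1 < 2 || n2 < 2) next
    j1 <- sum(xa); j2 <- sum(xb)
    if (j1 + j2 == 0 || j1 + j2 == n1 + n2) next
    p1 <- j1 / n1; p2 <- j2 / n2
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  num / den
}

# straightforward application of the stated greedy LD-pruning rule
oracle_ld_prune_window <- function(gm, idx, r2_max) {
  alive <- idx
  maf <- site_maf_oracle(gm)
  repeat {
    if (length(alive) < 2) break
    best <- NULL
    for (jj in 2:length(alive)) for (ii in 1:(jj - 1)) {
      r2 <- ld_r2(gm, alive[ii], alive[jj])
      if (!is.na(r2) && r2 > r2_max &&
          (is.null(best) || r2 > best$r2 + 1e-12))
        best <- list(i = alive[ii], j = alive[jj], r2 = r2)
    }
    if (is.null(best)) break
    drop <- if (maf[best$i] < maf[best$j]) best$i
      else if (maf[best$j] < maf[best$i]) best$j
      else max(best$i, best$j)
    alive <- setdiff(alive, drop)
  }
  alive
}

site_maf_oracle <- function(gm) {
  vapply(seq_len(n_sites(gm)), function(s) {
    x <- gm$geno[, s][!is.na(gm$geno[, s])]
    p <- sum(x) / (2 * length(x))
    min(p, 1 - p)
  }, numeric(1))
}

# tiny two-population split model (no admixture), sizes N, split at t
split_model <- function(N, t, n_dip = 10, mu = 1e-4, n_loci = 1000,
                        N_b = N) {
  demographic_model(
    pop_labels = c("A", "B"),
    sizes = c(A = N, B = N_b),
    events = data.frame(time = t, source = "B", dest1 = "A",
                        stringsAsFactors = FALSE),
    mutation_rate = mu, n_sites = n_loci,
    samples_per_pop = c(A = n_dip, B = n_dip))
}

single_pop_model <- function(N, n_dip = 5, mu = 1e-4, n_loci = 1000) {
  demographic_model(
    pop_labels = "A", sizes = c(A = N),
    events = data.frame(time = numeric(), source = character(),
                        dest1 = character(), stringsAsFactors = FALSE),
    mutation_rate = mu, n_sites = n_loci, samples_per_pop = c(A = n_dip))
}

topo_dist <- function(a, b) as.numeric(ape::dist.topo(a, b))
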