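#' Diploid genotype matrix
#'
#' The central in-memory representation of a biallelic SNP panel: an
#' `n_samples x n_sites` integer matrix of alternate-allele counts
#' (0, 1 or 2), with `NA` marking missing calls. Sites are identified by
#' `chrom:pos` and must be position-sorted within each chromosome; every
#' site must carry at least one called genotype.
#'
#' @param geno integer matrix, samples in rows, sites in columns; entries
#'   0/1/2 or `NA`.
#' @param sample_ids character vector of sample names (row order).
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based positions, one per site.
#' @param ref,alt optional reference/alternate alleles per site (single
#'   bases); defaults `"A"`/`"T"`. Kept only so VCF round-trips are
#'   bit-exact; polarity is never interpreted as ancestral/derived.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sample_ids, chrom, pos, ref = NULL, alt = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_sites <- ncol(geno)
  if (length(sample_ids) != nrow(geno))
    stop("sample_ids length does not match genotype rows")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (length(chrom) != n_sites || length(pos) != n_sites)
    stop("chrom/pos length does not match genotype columns")
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (n_sites > 0) {
    if (any(colSums(!is.na(geno)) == 0))
      stop("site(s) entirely missing: ",
           paste(utils::head(which(colSums(!is.na(geno)) == 0), 5), collapse = ", "))
    # sites must be grouped by chromosome and strictly increasing within it
    rl <- rle(as.character(chrom))
    if (anyDuplicated(rl$values))
      stop("sites of one chromosome must be contiguous")
    for (block in split(seq_len(n_sites), factor(chrom, levels = rl$values))) {
      p <- pos[block]
      if (any(diff(p) <= 0))
        stop("positions not strictly increasing within chromosome ",
             chrom[block[1]])
    }
  }
  if (is.null(ref)) ref <- rep("A", n_sites)
  if (is.null(alt)) alt <- rep("T", n_sites)
  rownames(geno) <- sample_ids
  colnames(geno) <- paste(chrom, pos, sep = ":")
  structure(
    list(geno = geno, sample_ids = as.character(sample_ids),
         chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites (%.1f%% missing)\n",
              n_samples(x), n_sites(x),
              if (length(x$geno)) 100 * mean(is.na(x$geno)) else 0))
  invisible(x)
}

#' Number of samples / sites in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(gm) length(gm$sample_ids)

#' @rdname n_samples
#' @export
n_sites <- function(gm) length(gm$chrom)

#' Site identifiers (`chrom:pos`) of a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return character vector.
#' @export
site_ids <- function(gm) paste(gm$chrom, gm$pos, sep = ":")

#' Missingness mask
#' @param gm a `genotype_matrix`.
#' @return logical matrix, `TRUE` where the call is missing.
#' @export
missing_mask <- function(gm) is.na(gm$geno)

#' Subset a genotype matrix by site or sample
#'
#' Subsetting by sample can leave sites with no called genotype; those
#' sites are dropped (the class invariant requires every site to have at
#' least one call).
#'
#' @param gm a `genotype_matrix`.
#' @param sites integer or logical index over sites.
#' @param samples integer, logical or character index over samples.
#' @return a `genotype_matrix`.
#' @export
subset_sites <- function(gm, sites) {
  idx <- seq_len(n_sites(gm))[sites]
  genotype_matrix(gm$geno[, idx, drop = FALSE], gm$sample_ids,
                  gm$chrom[idx], gm$pos[idx], gm$ref[idx], gm$alt[idx])
}

#' @rdname subset_sites
#' @export
subset_samples <- function(gm, samples) {
  if (is.character(samples)) samples <- match(samples, gm$sample_ids)
  if (anyNA(samples)) stop("unknown sample(s) in subset")
  g <- gm$geno[samples, , drop = FALSE]
  keep <- colSums(!is.na(g)) > 0
  genotype_matrix(g[, keep, drop = FALSE], gm$sample_ids[samples],
                  gm$chrom[keep], gm$pos[keep], gm$ref[keep], gm$alt[keep])
}

#' Population map
#'
#' Assigns every sample to exactly one group. Stored as a factor named by
#' sample id; every declared group level must contain at least one sample.
#'
#' @param samples character vector of sample ids.
#' @param groups character vector (or factor) of group labels, parallel to
#'   `samples`.
#' @param levels optional explicit ordering of the group labels.
#' @return an object of class `pop_map` (a named factor).
#' @export
pop_map <- function(samples, groups, levels = NULL) {
  if (length(samples) != length(groups))
    stop("samples and groups must have the same length")
  if (anyDuplicated(samples))
    stop("duplicate sample(s) in population map: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (is.null(levels)) levels <- unique(as.character(groups))
  f <- factor(as.character(groups), levels = levels)
  if (anyNA(f)) stop("group label outside declared level set")
  empty <- setdiff(levels, unique(as.character(f)))
  if (length(empty))
    stop("declared group(s) with no sample: ", paste(empty, collapse = ", "))
  names(f) <- as.character(samples)
  structure(f, class = c("pop_map", "factor"))
}

#' @export
print.pop_map <- function(x, ...) {
  cat("pop_map:", length(x), "samples in", nlevels(x), "groups\n")
  print(table(unclass(x)))
  invisible(x)
}

#' Check a population map against a genotype matrix
#'
#' Every sample of `gm` must be assigned exactly once; errors list the
#' offending samples.
#'
#' @param pm a `pop_map`.
#' @param gm a `genotype_matrix`.
#' @return `pm`, invisibly, if consistent.
#' @export
validate_popmap <- function(pm, gm) {
  miss <- setdiff(gm$sample_ids, names(pm))
  if (length(miss))
    stop("population map does not cover sample(s): ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(pm), gm$sample_ids)
  if (length(extra))
    stop("population map names unknown sample(s): ",
         paste(extra, collapse = ", "))
  invisible(pm)
}

#' Samples belonging to one group
#' @param pm a `pop_map`.
#' @param group a group label.
#' @return character vector of sample ids.
#' @export
group_samples <- function(pm, group) {
  if (!group %in% levels(pm)) stop("unknown group: ", group)
  names(pm)[as.character(pm) == group]
}
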