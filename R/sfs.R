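#' Site-frequency spectrum objects
#'
#' An `sfs` stores counts (possibly fractional after hypergeometric
#' projection) of sites by derived/minor-allele class over one or more
#' populations. Spectra over at most three populations are dense arrays;
#' larger joint spectra are sparse (a 0-based cell-index matrix plus a
#' mass vector), because a dense six-dimensional array would explode.
#'
#' @param pop_labels character vector of population labels.
#' @param shape integer vector, per-population projected haploid size + 1.
#' @param counts dense array of `dim = shape` (for <= 3 populations), or
#'   a list `list(cells = <matrix>, mass = <numeric>)` for sparse storage.
#' @param folded is the spectrum folded (indexed by minor allele)?
#' @param monomorphic_included do the boundary cells carry mass?
#' @return an object of class `sfs`.
#' @export
new_sfs <- function(pop_labels, shape, counts, folded = FALSE,
                    monomorphic_included = FALSE) {
  shape <- as.integer(shape)
  if (is.list(counts)) {
    stopifnot(is.matrix(counts$cells), length(counts$mass) == nrow(counts$cells))
    if (any(counts$mass < 0)) stop("negative SFS mass")
  } else {
    counts <- array(counts, dim = shape)
    if (any(counts < 0)) stop("negative SFS mass")
  }
  structure(list(pop_labels = as.character(pop_labels), shape = shape,
                 counts = counts, folded = folded,
                 monomorphic_included = monomorphic_included),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("sfs over {%s}, shape (%s), %s, total mass %.4g\n",
              paste(x$pop_labels, collapse = ", "),
              paste(x$shape, collapse = ", "),
              if (x$folded) "folded" else "unfolded", sfs_total(x)))
  invisible(x)
}

#' Total mass of a spectrum
#' @param sfs an `sfs`.
#' @return numeric scalar.
#' @export
sfs_total <- function(sfs) {
  if (is.list(sfs$counts)) sum(sfs$counts$mass) else sum(sfs$counts)
}

is_sparse_sfs <- function(sfs) is.list(sfs$counts)

# canonical folded image of 0-based cell rows (matrix n x P)
fold_cells <- function(cells, shape) {
  nmax <- shape - 1L
  comp <- sweep(-cells, 2, nmax, "+")
  d <- rowSums(cells)
  half <- sum(nmax) / 2
  flip <- d > half
  # at the fold axis, pick the lexicographically smaller representative
  tie <- d == half
  if (any(tie)) {
    cmp <- rep(0L, sum(tie))
    ci <- cells[tie, , drop = FALSE]; co <- comp[tie, , drop = FALSE]
    for (p in seq_len(ncol(cells))) {
      undecided <- cmp == 0L
      cmp[undecided & ci[, p] > co[, p]] <- 1L
      cmp[undecided & ci[, p] < co[, p]] <- -1L
    }
    flip[tie] <- cmp == 1L
  }
  cells[flip, ] <- comp[flip, , drop = FALSE]
  cells
}

#' Fold a spectrum onto minor-allele classes
#'
#' Each cell is mapped onto its complement-equivalent with the smaller
#' total allele count (ties broken lexicographically), and masses are
#' summed. Idempotent.
#'
#' @param sfs an `sfs`.
#' @return a folded `sfs`.
#' @export
fold_sfs <- function(sfs) {
  cells <- sfs_cells(sfs)
  folded_cells <- fold_cells(cells$cells, sfs$shape)
  out <- accumulate_sfs(sfs$pop_labels, sfs$shape, folded_cells, cells$mass)
  out$folded <- TRUE
  out$monomorphic_included <- sfs$monomorphic_included
  out
}

# materialise any sfs as cells + mass (0-based cells)
sfs_cells <- function(sfs) {
  if (is_sparse_sfs(sfs))
    return(list(cells = sfs$counts$cells, mass = sfs$counts$mass))
  idx <- which(sfs$counts != 0)
  cells <- arrayInd(idx, sfs$shape) - 1L
  list(cells = cells, mass = sfs$counts[idx])
}

# build an sfs (dense if small) from cells + mass, summing duplicates
accumulate_sfs <- function(pop_labels, shape, cells, mass) {
  if (length(shape) <= 3) {
    counts <- array(0, dim = shape)
    idx <- as.vector((cells %*% cumprod(c(1, shape[-length(shape)])))) + 1
    agg <- rowsum(mass, idx)
    counts[as.numeric(rownames(agg))] <- agg
    new_sfs(pop_labels, shape, counts)
  } else {
    key <- as.vector(cells %*% cumprod(c(1, shape[-length(shape)])))
    agg <- rowsum(mass, key)
    ukey <- as.numeric(rownames(agg))
    strides <- cumprod(c(1, shape[-length(shape)]))
    cc <- matrix(0L, nrow = length(ukey), ncol = length(shape))
    rem <- ukey
    for (p in rev(seq_along(shape))) {
      cc[, p] <- as.integer(rem %/% strides[p])
      rem <- rem %% strides[p]
    }
    new_sfs(pop_labels, shape, list(cells = cc, mass = as.vector(agg)))
  }
}

#' Build a site-frequency spectrum from genotypes
#'
#' Per site and group the alternate-allele count among called alleles is
#' down-projected to the target haploid size by the hypergeometric
#' expectation, so sites with missing data contribute fractional mass to
#' every compatible cell. Sites with fewer called alleles than the
#' projection size in any group are dropped. With `fold = TRUE` (the
#' default; REF/ALT polarity carries no ancestral information) cells are
#' mapped to their minor-allele-total equivalents.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [pop_map()].
#' @param groups group labels spanning the spectrum (default: all).
#' @param projection per-group projected haploid sample sizes. Default:
#'   the largest size at which at least 90 percent of sites remain, i.e.
#'   the 10th percentile of per-site called-allele counts, capped at the
#'   full size.
#' @param fold fold to minor-allele classes?
#' @return an `sfs` (dense for <= 3 groups, sparse otherwise).
#' @export
build_sfs <- function(gm, popmap, groups = levels(popmap), projection = NULL,
                      fold = TRUE) {
  validate_popmap(popmap, gm)
  if (n_sites(gm) < 1) stop("genotype matrix has no sites")
  glist <- lapply(groups, function(gr)
    gm$geno[group_samples(popmap, gr), , drop = FALSE])
  ncall <- lapply(glist, function(g) 2 * colSums(!is.na(g)))
  jalt <- lapply(glist, function(g) colSums(g, na.rm = TRUE))
  full <- vapply(glist, function(g) 2 * nrow(g), numeric(1))
  if (is.null(projection)) {
    projection <- vapply(seq_along(groups), function(k)
      min(full[k], stats::quantile(ncall[[k]], 0.1, type = 1)), numeric(1))
  }
  projection <- as.integer(projection)
  if (length(projection) != length(groups))
    stop("projection must give one haploid size per group")
  if (any(projection < 1) || any(projection > full))
    stop("projection sizes must lie in [1, 2 x group sample count]")
  ok <- rep(TRUE, n_sites(gm))
  for (k in seq_along(groups)) ok <- ok & ncall[[k]] >= projection[k]
  if (!any(ok))
    stop("no site has enough called alleles for the requested projection")
  sites <- which(ok)
  shape <- projection + 1L
  P <- length(groups)
  # fast path: complete data at full size needs no projection at all
  if (all(vapply(seq_len(P), function(k)
        projection[k] == full[k] && all(ncall[[k]][sites] == full[k]),
        logical(1)))) {
    cells <- vapply(seq_len(P), function(k) as.integer(jalt[[k]][sites]),
                    integer(length(sites)))
    if (length(sites) == 1) cells <- matrix(cells, nrow = 1)
    if (fold) cells <- fold_cells(cells, shape)
    out <- accumulate_sfs(groups, shape, cells, rep(1, length(sites)))
    out$folded <- fold
    out$monomorphic_included <- TRUE
    return(out)
  }
  # per-group hypergeometric projection vectors per site
  cells <- NULL; mass <- NULL
  cell_list <- vector("list", length(sites))
  mass_list <- vector("list", length(sites))
  for (si in seq_along(sites)) {
    s <- sites[si]
    vecs <- lapply(seq_len(P), function(k) {
      m <- projection[k]; n <- ncall[[k]][s]; j <- jalt[[k]][s]
      if (n == m) {
        v <- numeric(m + 1); v[j + 1] <- 1; v
      } else {
        stats::dhyper(0:m, j, n - j, m)
      }
    })
    mm <- vecs[[1]]
    if (P > 1) for (k in 2:P) mm <- outer(mm, vecs[[k]])
    nz <- which(mm > 0)
    cell_list[[si]] <- arrayInd(nz, shape) - 1L
    mass_list[[si]] <- mm[nz]
  }
  cells <- do.call(rbind, cell_list)
  mass <- unlist(mass_list)
  if (fold) cells <- fold_cells(cells, shape)
  out <- accumulate_sfs(groups, shape, cells, mass)
  out$folded <- fold
  out$monomorphic_included <- TRUE # boundary cells keep projected mass
  out
}

#' Marginalize a joint spectrum onto a subset of populations
#'
#' Sums counts over the dropped axes; total mass is conserved.
#'
#' @param sfs an `sfs`.
#' @param groups_subset non-empty subset of `sfs$pop_labels`.
#' @return an `sfs` over `groups_subset`.
#' @export
marginalize_sfs <- function(sfs, groups_subset) {
  if (length(groups_subset) == 0) stop("empty population subset")
  keep <- match(groups_subset, sfs$pop_labels)
  if (anyNA(keep)) stop("unknown population(s): ",
                        paste(groups_subset[is.na(keep)], collapse = ", "))
  cm <- sfs_cells(sfs)
  out <- accumulate_sfs(sfs$pop_labels[keep], sfs$shape[keep],
                        cm$cells[, keep, drop = FALSE], cm$mass)
  out$folded <- sfs$folded
  out$monomorphic_included <- sfs$monomorphic_included
  out
}

#' Expected unfolded single-population spectrum under neutrality
#'
#' The standard constant-size coalescent closed form
#' `E[xi_i] = theta / i` for `i = 1 .. n - 1`; used as an analytic oracle
#' for the simulator.
#'
#' @param n haploid sample size (>= 2).
#' @param theta population-scaled mutation rate `4 N mu` per locus.
#' @return numeric vector of expected counts for derived classes
#'   `1 .. n - 1`.
#' @export
expected_sfs_single_pop <- function(n, theta) {
  if (n < 2) stop("n must be >= 2")
  theta / seq_len(n - 1)
}

#' Serialize / read a spectrum as plain text
#'
#' Header lines carry population labels, shape and flags; body lines are
#' `cell-index-tuple TAB mass` with 0-based indices. The round-trip is
#' exact.
#'
#' @param sfs an `sfs`.
#' @param path file path.
#' @return `write_sfs`: `path`, invisibly. `read_sfs`: an `sfs`.
#' @export
write_sfs <- function(sfs, path) {
  cm <- sfs_cells(sfs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#pops", paste(sfs$pop_labels, collapse = " ")),
               paste("#shape", paste(sfs$shape, collapse = " ")),
               paste("#folded", sfs$folded),
               paste("#monomorphic", sfs$monomorphic_included)), con)
  if (nrow(cm$cells))
    writeLines(paste(apply(cm$cells, 1, paste, collapse = " "),
                     sprintf("%.17g", cm$mass), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  field <- function(tag) sub(paste0("#", tag, " "), "",
                             hdr[startsWith(hdr, paste0("#", tag))])
  pops <- strsplit(field("pops"), " ")[[1]]
  shape <- as.integer(strsplit(field("shape"), " ")[[1]])
  folded <- as.logical(field("folded"))
  mono <- as.logical(field("monomorphic"))
  if (length(body)) {
    parts <- strsplit(body, "\t")
    cells <- t(vapply(parts, function(p)
      as.integer(strsplit(p[1], " ")[[1]]), integer(length(shape))))
    if (length(shape) == 1) cells <- matrix(cells, ncol = 1)
    mass <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  } else {
    cells <- matrix(integer(), ncol = length(shape))
    mass <- numeric()
  }
  out <- accumulate_sfs(pops, shape, cells, mass)
  out$folded <- folded
  out$monomorphic_included <- mono
  out
}

#' All pairwise two-population folded spectra
#'
#' Builds the 15 (for six groups) two-dimensional spectra that the
#' composite-likelihood fit uses, together with the bookkeeping the fit
#' needs: the observed SNP count and the total number of loci the panel
#' derives from (when known, used to anchor the absolute scale of the
#' model through the expected number of segregating sites).
#'
#' @inheritParams build_sfs
#' @param n_total_loci total loci (variant + monomorphic), if known.
#' @return a list of class `pairwise_sfs`: `pairs` (2-column matrix of
#'   labels), `spectra` (list of folded 2-D `sfs`), `samples` (projected
#'   haploid sizes), `n_snps`, `n_total_loci`.
#' @export
build_pairwise_sfs <- function(gm, popmap, groups = levels(popmap),
                               projection = NULL, fold = TRUE,
                               n_total_loci = NULL) {
  validate_popmap(popmap, gm)
  if (is.null(projection)) {
    projection <- vapply(groups, function(gr) {
      g <- gm$geno[group_samples(popmap, gr), , drop = FALSE]
      nc <- 2 * colSums(!is.na(g))
      as.integer(min(2 * nrow(g), stats::quantile(nc, 0.1, type = 1)))
    }, integer(1))
  }
  names(projection) <- groups
  if (length(groups) == 1) { # degenerate case: one marginal spectrum
    spectra <- list(build_sfs(gm, popmap, groups, projection = projection,
                              fold = fold))
    names(spectra) <- groups
    return(structure(list(pairs = matrix(character(), ncol = 2),
                          spectra = spectra, samples = projection,
                          n_snps = n_sites(gm), n_total_loci = n_total_loci),
                     class = "pairwise_sfs"))
  }
  pairs <- t(utils::combn(groups, 2))
  spectra <- vector("list", nrow(pairs))
  for (q in seq_len(nrow(pairs))) {
    a <- pairs[q, 1]; b <- pairs[q, 2]
    spectra[[q]] <- build_sfs(gm, popmap, c(a, b),
                              projection = projection[c(a, b)], fold = fold)
  }
  names(spectra) <- paste(pairs[, 1], pairs[, 2], sep = "_")
  structure(list(pairs = pairs, spectra = spectra,
                 samples = projection, n_snps = n_sites(gm),
                 n_total_loci = n_total_loci),
            class = "pairwise_sfs")
}

#' @export
print.pairwise_sfs <- function(x, ...) {
  cat(sprintf("pairwise_sfs: %d pairs over {%s}, %d SNPs\n",
              nrow(x$pairs), paste(names(x$samples), collapse = ", "),
              x$n_snps))
  invisible(x)
}
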