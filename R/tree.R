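#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration (via ape's implementation) on a
#' symmetric non-negative distance matrix with at least three taxa.
#' Additive distances are recovered exactly. Negative branch lengths,
#' which NJ can produce on non-additive input, are clamped to zero and
#' flagged via the `clamped` attribute.
#'
#' @param dist symmetric numeric matrix with zero diagonal and taxon
#'   names, or a `dist` object.
#' @return an [ape::ape-package] `phylo` tree (unrooted).
#' @export
neighbor_joining <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(dist < -1e-12)) stop("distances must be non-negative")
  if (any(abs(diag(dist)) > 1e-12)) stop("distance diagonal must be zero")
  if (nrow(dist) < 3) stop("need at least three taxa")
  if (is.null(rownames(dist)))
    rownames(dist) <- colnames(dist) <- paste0("t", seq_len(nrow(dist)))
  tree <- ape::nj(stats::as.dist(dist))
  clamped <- tree$edge.length < 0
  if (any(clamped)) {
    message(sum(clamped), " negative NJ branch length(s) clamped to 0")
    tree$edge.length[clamped] <- 0
  }
  attr(tree, "clamped") <- any(clamped)
  tree
}

#' Root a tree on the edge leading to an outgroup leaf
#'
#' @param tree a `phylo` tree.
#' @param leaf_label tip label of the outgroup.
#' @return a rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, leaf_label) {
  if (!leaf_label %in% tree$tip.label)
    stop("no such leaf: ", leaf_label)
  ape::root(tree, outgroup = leaf_label, resolve.root = TRUE)
}

#' Write a tree in Newick format
#'
#' Standard Newick with branch lengths. Labels containing whitespace or
#' Newick metacharacters are single-quoted (ape's writer does not quote,
#' so such labels go through a placeholder substitution).
#'
#' @param tree a `phylo` tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  labs <- tree$tip.label
  needs_quote <- grepl("[][[:space:](),:;']", labs)
  if (any(needs_quote)) {
    placeholder <- sprintf("BAYBERRYQ%04dZ", seq_along(labs))
    tree$tip.label[needs_quote] <- placeholder[needs_quote]
    txt <- ape::write.tree(tree)
    for (i in which(needs_quote)) {
      quoted <- paste0("'", gsub("'", "''", labs[i]), "'")
      txt <- sub(placeholder[i], quoted, txt, fixed = TRUE)
    }
    writeLines(txt, path)
  } else {
    ape::write.tree(tree, file = path)
  }
  invisible(path)
}

#' Read a Newick tree
#' @param path path to a Newick file.
#' @return a `phylo` tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Neighbor-joining sample tree from genotypes
#'
#' Convenience wrapper: [allele_sharing_distance()] then
#' [neighbor_joining()], optionally rooted with an outgroup sample.
#'
#' @param gm a [genotype_matrix()] with >= 3 samples.
#' @param outgroup optional sample id to root with.
#' @return a `phylo` tree.
#' @export
genotype_nj_tree <- function(gm, outgroup = NULL) {
  tree <- neighbor_joining(allele_sharing_distance(gm))
  if (!is.null(outgroup)) tree <- root_with_outgroup(tree, outgroup)
  tree
}
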