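#' Read a VCF file into a genotype matrix
#'
#' Parses diploid GT fields into alternate-allele counts. `./.` and
#' half-calls (`0/.`, `./1`) are marked missing; phased (`0|1`) and
#' unphased (`0/1`) separators are equivalent. With `biallelic_only`
#' (the default) indel records and records with more than one ALT allele
#' are dropped.
#'
#' @param path path to a VCF 4.x file (plain or gzipped).
#' @param biallelic_only drop multiallelic and indel records?
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, biallelic_only = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec > 0 && (is.null(v@gt) || ncol(v@gt) < 2))
    stop("VCF has no sample genotype (GT) columns: ", path)
  samples <- if (!is.null(v@gt)) colnames(v@gt)[-1] else character()
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- rep(TRUE, n_rec)
  if (biallelic_only && n_rec > 0) {
    alt[is.na(alt)] <- ""
    keep <- !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
  }
  if (n_rec == 0 || !any(keep)) {
    return(genotype_matrix(
      matrix(integer(), nrow = length(samples), ncol = 0),
      samples, character(), integer()))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  code[gt == "0/0"] <- 0L
  code[gt == "0/1" | gt == "1/0"] <- 1L
  code[gt == "1/1"] <- 2L
  genotype_matrix(t(code), samples,
                  fix[, "CHROM"], as.integer(fix[, "POS"]),
                  fix[, "REF"], fix[, "ALT"])
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits a genotype-only VCF (GT format field, unphased separators,
#' `./.` for missing). Reading the file back with [read_vcf()]
#' reproduces genotypes, positions, sample order and missingness exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=bayberry",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")),
             con)
  if (n_sites(gm) > 0) {
    gt <- matrix("./.", nrow = n_sites(gm), ncol = n_samples(gm))
    g <- t(gm$geno)
    gt[!is.na(g) & g == 0L] <- "0/0"
    gt[!is.na(g) & g == 1L] <- "0/1"
    gt[!is.na(g) & g == 2L] <- "1/1"
    lines <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".",
                   "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a two-column population map file
#'
#' Whitespace- or tab-delimited text, one `sample group` pair per line.
#' The map must cover every sample of `gm` exactly once; unknown samples,
#' duplicates and uncovered samples are reported by name.
#'
#' @param path path to the map file.
#' @param gm the [genotype_matrix()] the map is paired with.
#' @return a [pop_map()].
#' @export
read_popmap <- function(path, gm) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("sample", "group"),
                           colClasses = "character")
  dup <- unique(tab$sample[duplicated(tab$sample)])
  if (length(dup)) stop("duplicate sample(s) in ", path, ": ",
                        paste(dup, collapse = ", "))
  pm <- pop_map(tab$sample, tab$group)
  validate_popmap(pm, gm)
  pm
}

#' Write a population map file
#' @param pm a [pop_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path) {
  utils::write.table(data.frame(sample = names(pm), group = as.character(pm)),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(path)
}
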