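#' Construct a genotype matrix
#'
#' The package's central container for diploid biallelic SNP genotypes:
#' a sites-by-samples integer matrix of alternate-allele dosages
#' (0, 1, 2, or `NA` for a missing call) together with per-site scaffold,
#' 1-based position and ref/alt alleles.
#'
#' @param geno integer matrix, sites in rows, samples in columns; entries in
#'   `{0, 1, 2, NA}`. Column names are the sample ids.
#' @param chrom character vector of scaffold ids, one per site.
#' @param pos integer vector of 1-based positions, strictly increasing within
#'   each scaffold.
#' @param ref,alt single-character reference / alternate alleles per site.
#' @param info optional data.frame of per-site INFO annotations (e.g. QD, FS,
#'   MQ) used by [filter_variants()].
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, chrom, pos, ref = NULL, alt = NULL,
                            info = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  rownames(geno) <- NULL
  n <- nrow(geno)
  if (length(chrom) != n || length(pos) != n)
    stop("chrom/pos length must equal nrow(geno)")
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("sample", seq_len(ncol(geno)))
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  for (sc in unique(chrom)) {
    p <- pos[chrom == sc]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within scaffold ", sc)
  }
  structure(list(geno = geno, chrom = as.character(chrom),
                 pos = as.integer(pos), ref = as.character(ref),
                 alt = as.character(alt), samples = colnames(geno),
                 info = info),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "biallelic sites x",
      ncol(x$geno), "samples on", length(unique(x$chrom)), "scaffold(s)\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by sites and/or samples
#'
#' @param x a `genotype_matrix`.
#' @param sites logical or integer index over sites (rows).
#' @param samples character, logical or integer index over samples.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(sites)) sites <- seq_len(nrow(x$geno))
  if (is.null(samples)) samples <- x$samples
  if (is.character(samples)) {
    missing_s <- setdiff(samples, x$samples)
    if (length(missing_s))
      stop("unknown sample(s): ", paste(missing_s, collapse = ", "))
  }
  genotype_matrix(x$geno[sites, samples, drop = FALSE],
                  x$chrom[sites], x$pos[sites], x$ref[sites], x$alt[sites],
                  info = if (!is.null(x$info)) x$info[sites, , drop = FALSE])
}

#' Read a population map
#'
#' A population map assigns each sample to a population (e.g. wild or
#' domestic herds). Tab-separated with a header; columns `sample`,
#' `population`, and optionally `status`.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `sample`, `population` (and `status` if
#'   present).
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "population") %in% names(pm)))
    stop("population map needs 'sample' and 'population' columns")
  pm
}

#' @rdname read_popmap
#' @param popmap data.frame as returned by `read_popmap`.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(popmap, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
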