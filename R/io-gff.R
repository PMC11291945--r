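#' Read gene and exon spans from a GFF3 file
#'
#' Parses a GFF3 annotation (via \code{ape::read.gff}) and returns the
#' feature spans converted to the package's internal 0-based half-open
#' convention (GFF is 1-based closed). The gene id is taken from the `ID=`
#' attribute (falling back to `Name=`).
#'
#' @param path path to the GFF3 file.
#' @param feature feature types to keep (default `"gene"`; use `"exon"` for
#'   the coding mask used in CNE discovery).
#' @return data.frame `chrom`, `start`, `end`, `strand`, `gene_id`.
#' @export
read_gff3 <- function(path, feature = "gene") {
  gff <- ape::read.gff(path)
  gff <- gff[gff$type %in% feature, , drop = FALSE]
  id <- sub(".*ID=([^;]+).*", "\\1", gff$attributes)
  noid <- !grepl("ID=", gff$attributes)
  id[noid] <- sub(".*Name=([^;]+).*", "\\1", gff$attributes[noid])
  data.frame(chrom = as.character(gff$seqid),
             start = gff$start - 1L, end = gff$end,
             strand = as.character(gff$strand), gene_id = id)
}

#' Write gene spans as GFF3
#'
#' @param genes data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `gene_id`, and optionally `type` (default `"gene"`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  type <- if ("type" %in% names(genes)) genes$type else rep("gene",
                                                            nrow(genes))
  lines <- sprintf("%s\tdomestiscan\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chrom, type, genes$start + 1L, genes$end,
                   genes$strand, genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `name` / `score` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  cols <- list(df$chrom, df$start, df$end)
  if ("name" %in% names(df)) cols <- c(cols, list(df$name))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
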