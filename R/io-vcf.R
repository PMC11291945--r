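#' Read a VCF into a genotype matrix
#'
#' Parses a VCF v4.x file and returns the biallelic SNP records as a
#' [genotype_matrix()]. Multi-allelic records and indels are skipped and their
#' counts reported via a message. Genotypes are read from the GT field;
#' `./.` (or `.`) becomes a missing dosage. Phasing is ignored. Per-site INFO
#' annotations QD, FS, MQ, MQRankSum and ReadPosRankSum are carried along when
#' present so the matrix can be passed to [filter_variants()].
#'
#' Scaffold lengths declared in `##contig` header lines are attached as the
#' `scaffold_lengths` attribute (named integer vector).
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param verbose print skip counts.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, verbose = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (nrow(v@gt) == 0 || !("FORMAT" %in% colnames(v@gt)))
    stop("VCF has no genotype (GT) columns")
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  n_skip <- sum(!snp)
  if (verbose && n_skip > 0)
    message("read_vcf: skipped ", n_skip, " non-biallelic-SNP record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  # dosage = count of '1' alleles; any missing allele => NA
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dos[gt_clean == "0/0"] <- 0L
  dos[gt_clean %in% c("0/1", "1/0")] <- 1L
  dos[gt_clean == "1/1"] <- 2L

  info_keys <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
  info_raw <- fix[snp, "INFO"]
  info <- as.data.frame(lapply(info_keys, function(k) {
    m <- regmatches(info_raw,
                    regexpr(paste0("(^|;)", k, "=[^;]*"), info_raw))
    out <- rep(NA_real_, length(info_raw))
    hit <- grepl(paste0("(^|;)", k, "="), info_raw)
    out[hit] <- suppressWarnings(as.numeric(sub(paste0(".*", k, "="), "", m)))
    out
  }))
  names(info) <- info_keys

  g <- genotype_matrix(dos, chrom = fix[snp, "CHROM"],
                       pos = as.integer(fix[snp, "POS"]),
                       ref = ref[snp], alt = alt[snp], info = info)
  meta <- v@meta
  contig <- meta[grepl("^##contig=", meta)]
  if (length(contig)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", contig)
    lens <- suppressWarnings(as.integer(sub(".*length=([0-9]+).*", "\\1",
                                            contig)))
    attr(g, "scaffold_lengths") <- stats::setNames(lens, ids)
  }
  g
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a minimal but valid VCF v4.2 with `##contig` lines (from
#' `scaffold_lengths`), per-site INFO fields when the matrix carries them, and
#' unphased GT genotypes. The output is byte-deterministic for a given matrix.
#'
#' @param g a `genotype_matrix`.
#' @param path output path.
#' @param scaffold_lengths named integer vector; defaults to the matrix's
#'   `scaffold_lengths` attribute, else the maximum position per scaffold.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, scaffold_lengths = attr(g, "scaffold_lengths")) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(scaffold_lengths)) {
    scaffold_lengths <- tapply(g$pos, g$chrom, max)
    scaffold_lengths <- scaffold_lengths[unique(g$chrom)]
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=domestiscan",
           sprintf("##contig=<ID=%s,length=%d>", names(scaffold_lengths),
                   as.integer(scaffold_lengths)),
           '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
           '##INFO=<ID=FS,Number=1,Type=Float,Description="FisherStrand">',
           '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$samples), collapse = "\t"))
  if (is.null(g$info)) {
    info_col <- rep(".", nrow(g$geno))
  } else {
    fmt_num <- function(x) ifelse(is.na(x), NA,
                                  formatC(x, format = "g", digits = 6))
    keys <- names(g$info)
    parts <- mapply(function(k, col) {
      v <- fmt_num(col)
      ifelse(is.na(v), NA, paste0(k, "=", v))
    }, keys, g$info, SIMPLIFY = FALSE)
    info_col <- apply(do.call(cbind, parts), 1, function(r)
      if (all(is.na(r))) "." else paste(r[!is.na(r)], collapse = ";"))
  }
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g$geno + 1L],
                   nrow = nrow(g$geno))
  gt_str[is.na(gt_str)] <- "./."
  body <- paste(g$chrom, g$pos, ".", g$ref, g$alt, ".", "PASS", info_col,
                "GT", apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
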