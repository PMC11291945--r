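#' Construct an alignment segment
#'
#' A slice of a focal-referenced multi-species alignment: a character matrix
#' of aligned rows (residues and `-` gaps), one row per species, plus the
#' focal coordinates the columns map to. The focal species' row may consist
#' entirely of gaps — the signature of a focal-lineage deletion — in which
#' case `start == end` marks the deletion point.
#'
#' @param rows character matrix (species x columns) of single characters, with
#'   species ids as row names; absent species are simply not included.
#' @param chrom focal scaffold id.
#' @param start,end focal coordinates (0-based half-open).
#' @param focal id of the focal species.
#' @return object of class `alignment_segment`.
#' @export
alignment_segment <- function(rows, chrom, start, end, focal) {
  stopifnot(is.matrix(rows), !is.null(rownames(rows)))
  structure(list(rows = rows, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), focal = focal),
            class = "alignment_segment")
}

#' @export
print.alignment_segment <- function(x, ...) {
  cat(sprintf("alignment_segment %s:%d-%d, %d species x %d columns\n",
              x$chrom, x$start, x$end, nrow(x$rows), ncol(x$rows)))
  invisible(x)
}

.revcomp_chars <- function(v) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N", "-" = "-",
           a = "t", c = "g", g = "c", t = "a", n = "n")
  rev(unname(map[v]))
}

#' Read a MAF multiple alignment
#'
#' Parses a Multiple Alignment Format file into a list of
#' [alignment_segment()]s, one per block. The first `s` line of each block is
#' taken as the focal reference; blocks whose focal row is on the minus
#' strand are normalised to the plus strand by reverse-complementing every
#' row and recomputing the focal start. Focal rows of size 0 (all-gap text)
#' are kept and mark focal-lineage deletions. MAF starts are 0-based.
#'
#' @param path path to the MAF file.
#' @return list of `alignment_segment` objects (empty list for an empty
#'   file).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  segs <- list()
  block <- list()
  flush <- function(block) {
    if (!length(block)) return(NULL)
    sp <- vapply(block, `[[`, "", "species")
    seqs <- vapply(block, `[[`, "", "text")
    w <- unique(nchar(seqs))
    if (length(w) != 1)
      stop("inconsistent row lengths in block starting at ",
           block[[1]]$src, ":", block[[1]]$start)
    rows <- do.call(rbind, strsplit(seqs, ""))
    rownames(rows) <- sp
    foc <- block[[1]]
    start <- foc$start; size <- foc$size
    if (foc$strand == "-") {
      rows <- t(apply(rows, 1, .revcomp_chars))
      rownames(rows) <- sp
      start <- foc$srcSize - (foc$start + foc$size)
    }
    chrom <- sub("^[^.]*\\.", "", foc$src)
    alignment_segment(rows, chrom, start, start + size,
                      focal = sub("\\..*$", "", foc$src))
  }
  for (ln in lines) {
    if (grepl("^a", ln)) {
      s <- flush(block); if (!is.null(s)) segs[[length(segs) + 1L]] <- s
      block <- list()
    } else if (grepl("^s\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      block[[length(block) + 1L]] <- list(
        src = f[2], start = as.integer(f[3]), size = as.integer(f[4]),
        strand = f[5], srcSize = as.integer(f[6]),
        species = sub("\\..*$", "", f[2]), text = f[7])
    }
  }
  s <- flush(block); if (!is.null(s)) segs[[length(segs) + 1L]] <- s
  segs
}

#' Write alignment segments as MAF
#'
#' One block per segment, `s` lines only, focal species first, plus strand,
#' 0-based starts. Non-focal rows are written with start 0 and their own
#' ungapped length as size (their true source coordinates are not tracked by
#' the simulator).
#'
#' @param segments list of `alignment_segment` objects.
#' @param path output path.
#' @param scaffold_lengths named vector giving the focal source sizes.
#' @return `path`, invisibly.
#' @export
write_maf <- function(segments, path, scaffold_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  for (seg in segments) {
    writeLines("a score=0", con)
    sp <- rownames(seg$rows)
    ord <- c(which(sp == seg$focal), which(sp != seg$focal))
    for (i in ord) {
      txt <- paste(seg$rows[i, ], collapse = "")
      ungapped <- sum(seg$rows[i, ] != "-")
      if (sp[i] == seg$focal) {
        src <- paste0(seg$focal, ".", seg$chrom)
        writeLines(sprintf("s %s %d %d + %d %s", src, seg$start,
                           seg$end - seg$start,
                           scaffold_lengths[[seg$chrom]], txt), con)
      } else {
        writeLines(sprintf("s %s.%s %d %d + %d %s", sp[i], "chr1", 0L,
                           ungapped, ungapped, txt), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}

# focal coordinate of each alignment column (0-based). Gap columns take the
# coordinate of the next focal base (i.e. the insertion point).
focal_column_coords <- function(seg) {
  foc <- seg$rows[seg$focal, ]
  nongap <- foc != "-"
  seg$start + cumsum(nongap) - as.integer(nongap)
}
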