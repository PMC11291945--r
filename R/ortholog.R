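#' Read / write protein FASTA
#'
#' Thin wrappers over Biostrings returning/accepting a named character
#' vector of amino-acid sequences.
#'
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}

#' @rdname read_proteome
#' @param seqs named character vector of protein sequences.
#' @export
write_proteome <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path,
                              width = 60)
  invisible(path)
}

# all-vs-all local alignment scores (BLOSUM62, gap open 11 / extend 1);
# rows = a, cols = b
.score_matrix <- function(a, b, gap_open = 11, gap_extend = 1) {
  bset <- Biostrings::AAStringSet(b)
  m <- matrix(NA_real_, length(a), length(b),
              dimnames = list(names(a), names(b)))
  for (i in seq_along(a)) {
    m[i, ] <- Biostrings::pairwiseAlignment(
      bset, Biostrings::AAString(a[[i]]), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = gap_open,
      gapExtension = gap_extend, scoreOnly = TRUE)
  }
  m
}

#' Reciprocal best hits between two proteomes
#'
#' Scores every protein pair by Smith-Waterman local alignment under
#' BLOSUM62 (gap open 11, extend 1) and keeps pair (a, b) iff b is the
#' unique best-scoring hit of a in B and a the unique best of b in A —
#' the standard one-to-one orthology criterion. A protein with tied best
#' hits is left unpaired.
#'
#' @param proteome_a,proteome_b named character vectors of protein
#'   sequences.
#' @param gap_open,gap_extend gap penalties.
#' @return data.frame `id_a`, `id_b`, `score`.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b, gap_open = 11,
                                 gap_extend = 1) {
  if (!length(proteome_a) || !length(proteome_b)) stop("empty proteome")
  m <- .score_matrix(proteome_a, proteome_b, gap_open, gap_extend)
  unique_max <- function(x) {
    w <- which(x == max(x))
    if (length(w) == 1) w else NA_integer_
  }
  best_b <- apply(m, 1, unique_max)   # best hit in B for each a
  best_a <- apply(m, 2, unique_max)   # best hit in A for each b
  keep <- which(!is.na(best_b) & !is.na(best_a[best_b]) &
                  best_a[best_b] == seq_along(best_b))
  data.frame(id_a = names(proteome_a)[keep],
             id_b = names(proteome_b)[best_b[keep]],
             score = m[cbind(keep, best_b[keep])])
}

# project a partner sequence onto focal columns via global alignment;
# partner residues aligned to focal-gap columns (insertions) are dropped
.project_onto_focal <- function(focal_seq, partner_seq, gap_open = 11,
                                gap_extend = 1) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(partner_seq), Biostrings::AAString(focal_seq),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend)
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  pat[sub != "-"]   # one entry per focal residue ('-' = deletion in partner)
}

#' Build focal-anchored one-to-one ortholog groups
#'
#' For each non-focal proteome, reciprocal best hits against the focal
#' proteome define one-to-one partners. A focal gene forms a group when it
#' has a partner in at least `min_species` of the non-focal proteomes. Each
#' group carries a stacked alignment: each partner is globally aligned to
#' the focal protein and projected onto focal columns, so the alignment has
#' exactly one column per focal residue (partner insertions are discarded).
#'
#' @param focal_proteome named character vector (the focal species).
#' @param other_proteomes named list of named character vectors, one per
#'   non-focal species.
#' @param min_species minimum number of non-focal species with a partner
#'   (default: all of them).
#' @param gap_open,gap_extend alignment gap penalties.
#' @return named list of groups; each is a list with `gene` (focal id),
#'   `alignment` (character matrix, rows = focal + partner species,
#'   columns = focal residues) and `n_partners`.
#' @export
build_ortholog_groups <- function(focal_proteome, other_proteomes,
                                  min_species = length(other_proteomes),
                                  gap_open = 11, gap_extend = 1) {
  rbh <- lapply(other_proteomes, function(p)
    reciprocal_best_hits(focal_proteome, p, gap_open, gap_extend))
  groups <- list()
  for (gene in names(focal_proteome)) {
    partners <- lapply(rbh, function(tb) tb$id_b[match(gene, tb$id_a)])
    have <- !vapply(partners, is.na, TRUE)
    if (sum(have) < min_species) next
    foc_seq <- focal_proteome[[gene]]
    aln <- matrix("-", nrow = 1 + sum(have), ncol = nchar(foc_seq),
                  dimnames = list(c("focal", names(other_proteomes)[have]),
                                  NULL))
    aln[1, ] <- strsplit(foc_seq, "")[[1]]
    for (sp in names(other_proteomes)[have]) {
      pseq <- other_proteomes[[sp]][[partners[[sp]]]]
      aln[sp, ] <- .project_onto_focal(foc_seq, pseq, gap_open, gap_extend)
    }
    groups[[gene]] <- list(gene = gene, alignment = aln,
                           n_partners = sum(have))
  }
  groups
}

#' Scan an ortholog group for focal-specific substitutions
#'
#' A focal-protein column is called when (i) every non-focal row carries one
#' identical residue (a gap anywhere disqualifies), (ii) the focal residue
#' differs from it, and (iii) the flank similarity — the mean, over the 10
#' columns upstream and 10 downstream, of the fraction of all rows matching
#' the column-majority residue — exceeds `flank_min_sim` (default 0.6).
#' Columns within `flank` residues of either protein end are never called
#' (their flank is undefined). `flank_mode = "split"` instead requires each
#' 10-column flank to exceed the threshold separately.
#'
#' @param group one group from [build_ortholog_groups()].
#' @param flank flank width in columns on each side (default 10).
#' @param flank_min_sim minimum flank similarity (default 0.6).
#' @param flank_mode `"joint"` (one 20-column window) or `"split"`.
#' @return data.frame `gene`, `column` (1-based focal coordinate),
#'   `focal_residue`, `consensus_residue`, `flank_similarity`.
#' @export
scan_specific_substitutions <- function(group, flank = 10L,
                                        flank_min_sim = 0.6,
                                        flank_mode = c("joint", "split")) {
  flank_mode <- match.arg(flank_mode)
  aln <- group$alignment
  L <- ncol(aln)
  empty <- data.frame(gene = character(), column = integer(),
                      focal_residue = character(),
                      consensus_residue = character(),
                      flank_similarity = numeric())
  if (L < 2 * flank + 1 || nrow(aln) < 2) return(empty)
  col_majority_frac <- vapply(seq_len(L), function(j) {
    col <- aln[, j]; col <- col[col != "-"]
    if (!length(col)) return(0)
    tab <- table(col)
    max(tab) / nrow(aln)
  }, 0)
  nf <- aln[-1, , drop = FALSE]
  calls <- list()
  for (j in (flank + 1L):(L - flank)) {
    col <- nf[, j]
    if (any(col == "-")) next
    if (length(unique(col)) != 1) next
    cons <- col[1]
    if (aln[1, j] == "-" || aln[1, j] == cons) next
    up <- col_majority_frac[(j - flank):(j - 1)]
    down <- col_majority_frac[(j + 1):(j + flank)]
    pass <- if (flank_mode == "joint") mean(c(up, down)) > flank_min_sim
    else mean(up) > flank_min_sim && mean(down) > flank_min_sim
    if (!pass) next
    calls[[length(calls) + 1L]] <- data.frame(
      gene = group$gene, column = j, focal_residue = aln[1, j],
      consensus_residue = cons,
      flank_similarity = if (flank_mode == "joint") mean(c(up, down))
      else min(mean(up), mean(down)))
  }
  if (!length(calls)) return(empty)
  do.call(rbind, calls)
}

#' Scan all ortholog groups
#'
#' @param groups list from [build_ortholog_groups()].
#' @param ... passed to [scan_specific_substitutions()].
#' @return combined data.frame of substitution sites across groups.
#' @export
scan_all_groups <- function(groups, ...) {
  res <- lapply(groups, scan_specific_substitutions, ...)
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene = character(), column = integer(),
                      focal_residue = character(),
                      consensus_residue = character(),
                      flank_similarity = numeric())
  rownames(out) <- NULL
  out
}

#' Genes carrying at least one focal-specific substitution
#'
#' @param sites data.frame from [scan_all_groups()].
#' @return list with `genes` (sorted distinct gene ids) and `count`.
#' @export
genes_with_substitutions <- function(sites) {
  g <- sort(unique(sites$gene))
  list(genes = g, count = length(g))
}
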