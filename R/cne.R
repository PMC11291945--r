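#' Excise coding columns and split alignment segments
#'
#' Removes every alignment column whose focal coordinate falls inside an
#' annotated exon, splits the remaining columns into maximal contiguous
#' runs, and drops runs shorter than `min_len` columns. What survives is the
#' noncoding portion of the alignment from which conserved noncoding
#' elements are called.
#'
#' @param segments list of [alignment_segment()] objects (focal-referenced).
#' @param exons data.frame of exon spans on focal coordinates
#'   ([read_gff3()] with `feature = "exon"`); 0-based half-open.
#' @param min_len minimum segment length in alignment columns (default 50).
#' @return list of `alignment_segment` objects.
#' @export
extract_noncoding_segments <- function(segments, exons, min_len = 50L) {
  out <- list()
  known <- unique(exons$chrom)
  for (seg in segments) {
    if (length(known) && !(seg$chrom %in% known))
      warning("scaffold ", seg$chrom,
              " absent from annotation; segment kept as noncoding",
              call. = FALSE)
    coords <- focal_column_coords(seg)
    coding <- rep(FALSE, length(coords))
    ex <- exons[exons$chrom == seg$chrom, , drop = FALSE]
    for (i in seq_len(nrow(ex)))
      coding <- coding | (coords >= ex$start[i] & coords < ex$end[i])
    r <- rle(!coding)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      cols <- starts[k]:ends[k]
      rows <- seg$rows[, cols, drop = FALSE]
      foc_nongap <- rows[seg$focal, ] != "-"
      cc <- coords[cols]
      if (any(foc_nongap)) {
        s <- min(cc[foc_nongap]); e <- max(cc[foc_nongap]) + 1L
      } else {
        s <- cc[1]; e <- cc[1]    # focal-deleted: anchor point
      }
      out[[length(out) + 1L]] <- alignment_segment(rows, seg$chrom, s, e,
                                                   seg$focal)
    }
  }
  out
}

#' Column-majority conservation of an alignment segment
#'
#' For each column, the fraction of the chosen species whose residue equals
#' the subset's column-majority residue (the most frequent non-gap residue;
#' lexicographic tie-break); gaps and species absent from the segment count
#' as mismatches. The score is the mean of these fractions over columns —
#' 1.0 means every chosen species identical at every column.
#'
#' @param seg an `alignment_segment`.
#' @param species_subset character vector of species ids (>= 2) over which
#'   conservation is scored.
#' @return fraction in `[0, 1]`.
#' @export
conservation_score <- function(seg, species_subset) {
  if (length(species_subset) < 2) stop("need >= 2 species")
  present <- intersect(species_subset, rownames(seg$rows))
  nsub <- length(species_subset)
  if (!length(present) || ncol(seg$rows) == 0) return(0)
  sub <- seg$rows[present, , drop = FALSE]
  mean(apply(sub, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(0)
    tab <- table(col)
    maj <- names(tab)[tab == max(tab)][1]   # lexicographic tie-break
    sum(col == maj) / nsub
  }))
}

#' Find candidate conserved noncoding elements
#'
#' A noncoding segment becomes a candidate CNE when its conservation over
#' the non-focal species exceeds `min_similarity` (default 0.8, i.e. the
#' ">80% similarity" rule) and it is at least `min_len` columns long.
#'
#' @param segments list of noncoding `alignment_segment`s (from
#'   [extract_noncoding_segments()]).
#' @param species full species roster (absent species score as mismatches).
#' @param focal focal species id.
#' @param min_similarity conservation threshold over non-focal species.
#' @param min_len minimum element length in alignment columns.
#' @return data.frame `chrom`, `start`, `end`, `segment` (index into
#'   `segments`), `nonfocal_conservation`, `class = "conserved"`.
#' @export
find_conserved_elements <- function(segments, species, focal,
                                    min_similarity = 0.8, min_len = 50L) {
  nonfocal <- setdiff(species, focal)
  rows <- lapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    if (ncol(seg$rows) < min_len) return(NULL)
    cons <- conservation_score(seg, nonfocal)
    if (cons <= min_similarity) return(NULL)
    data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
               segment = i, nonfocal_conservation = cons,
               class = "conserved")
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), segment = integer(),
                      nonfocal_conservation = numeric(),
                      class = character()))
  do.call(rbind, rows)
}

# per-segment focal-row summary used by the classifiers
.focal_state <- function(seg) {
  if (!(seg$focal %in% rownames(seg$rows)))
    return(list(absent = TRUE, gap_fraction = 1))
  foc <- seg$rows[seg$focal, ]
  list(absent = FALSE, gap_fraction = mean(foc == "-"))
}

#' Classify lost (focal-deleted) conserved elements
#'
#' A candidate CNE is lost when the focal species' row is absent from the
#' alignment or is gap in more than `max_focal_gap` of its columns — a
#' conserved element every other species retains but the focal genome does
#' not.
#'
#' @param cnes candidate table from [find_conserved_elements()].
#' @param segments the segment list the candidates index into.
#' @param max_focal_gap gap fraction above which the focal row counts as
#'   lost (default 0.8).
#' @return the lost subset of `cnes` with `class = "lost"` and a
#'   `focal_gap_fraction` column.
#' @export
classify_lost <- function(cnes, segments, max_focal_gap = 0.8) {
  st <- lapply(cnes$segment, function(i) .focal_state(segments[[i]]))
  lost <- vapply(st, function(s) s$absent || s$gap_fraction > max_focal_gap,
                 TRUE)
  out <- cnes[lost, , drop = FALSE]
  out$class <- rep("lost", nrow(out))
  out$focal_gap_fraction <- vapply(st[lost], `[[`, 0, "gap_fraction")
  out
}

# longest run of focal-variant columns plus the all-species conservation
.divergence_profile <- function(seg, species, focal, min_column_support) {
  nonfocal <- setdiff(species, focal)
  present_nf <- intersect(nonfocal, rownames(seg$rows))
  if (!(seg$focal %in% rownames(seg$rows)) || !length(present_nf))
    return(list(max_run = 0L, all_conservation = NA_real_))
  foc <- seg$rows[focal, ]
  nf <- seg$rows[present_nf, , drop = FALSE]
  variant <- vapply(seq_len(ncol(nf)), function(j) {
    col <- nf[, j]; col <- col[col != "-"]
    if (!length(col)) return(FALSE)
    tab <- table(col)
    maj <- names(tab)[tab == max(tab)][1]
    support <- sum(col == maj) / length(nonfocal)
    support >= min_column_support && foc[j] != "-" && foc[j] != maj
  }, TRUE)
  r <- rle(variant)
  max_run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  list(max_run = as.integer(max_run),
       all_conservation = conservation_score(seg, species))
}

#' Classify divergent conserved elements
#'
#' A column is a focal-variant column when at least `min_column_support` of
#' the non-focal species share one majority residue and the focal residue is
#' present but differs from it. A candidate CNE is divergent when it carries
#' a run of at least `min_contiguous` consecutive focal-variant columns
#' (default 10) and its conservation over all species — focal row included —
#' exceeds `min_all_conservation` (default 0.8).
#'
#' @param cnes candidate table from [find_conserved_elements()].
#' @param segments the segment list the candidates index into.
#' @param species full species roster.
#' @param focal focal species id.
#' @param min_contiguous minimum run of focal-variant columns.
#' @param min_all_conservation all-species conservation threshold.
#' @param min_column_support non-focal majority support per variant column.
#' @return the divergent subset with `class = "divergent"`,
#'   `max_contiguous_focal_variants` and `all_species_conservation` columns.
#' @export
classify_divergent <- function(cnes, segments, species, focal,
                               min_contiguous = 10L,
                               min_all_conservation = 0.8,
                               min_column_support = 0.8) {
  prof <- lapply(cnes$segment, function(i)
    .divergence_profile(segments[[i]], species, focal, min_column_support))
  run <- vapply(prof, `[[`, 0L, "max_run")
  cons <- vapply(prof, `[[`, 0, "all_conservation")
  div <- run >= min_contiguous & !is.na(cons) & cons > min_all_conservation
  out <- cnes[div, , drop = FALSE]
  out$class <- rep("divergent", nrow(out))
  out$max_contiguous_focal_variants <- run[div]
  out$all_species_conservation <- cons[div]
  out
}

#' Nearest-gene assignment for CNEs or regions
#'
#' Each element is assigned the gene whose span minimises the distance from
#' the element midpoint (0 when the midpoint lies inside the span). The
#' distance is signed relative to the gene's annotated strand: negative
#' means the element lies upstream of the gene start. Equidistant genes are
#' all reported (one row each); elements on scaffolds without genes get
#' `gene_id = "none"`.
#'
#' @param cnes data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param genes data.frame from [read_gff3()].
#' @return data.frame: the input columns plus `element` (row index of
#'   `cnes`), `gene_id`, `distance`.
#' @export
nearest_gene <- function(cnes, genes) {
  rows <- lapply(seq_len(nrow(cnes)), function(i) {
    mid <- (cnes$start[i] + cnes$end[i]) / 2
    gg <- genes[genes$chrom == cnes$chrom[i], , drop = FALSE]
    base <- data.frame(element = i, chrom = cnes$chrom[i],
                       start = cnes$start[i], end = cnes$end[i])
    if (nrow(gg) == 0)
      return(cbind(base, gene_id = "none", distance = NA_real_))
    d_abs <- pmax(gg$start - mid, mid - gg$end, 0)
    best <- which(d_abs == min(d_abs))
    signed <- vapply(best, function(k) {
      if (d_abs[k] == 0) return(0)
      if (gg$strand[k] == "-") {
        if (mid > gg$end[k]) -(mid - gg$end[k]) else gg$start[k] - mid
      } else {
        if (mid < gg$start[k]) mid - gg$start[k] else mid - gg$end[k]
      }
    }, 0)
    cbind(base, gene_id = gg$gene_id[best], distance = signed)
  })
  do.call(rbind, rows)
}

#' Hypergeometric term enrichment with BH correction
#'
#' Upper-tail hypergeometric test of each annotation term's overlap with a
#' gene set against a background, Benjamini-Hochberg adjusted across terms.
#' The annotation source is the caller's (any gene-to-term map).
#'
#' @param gene_set character vector, a subset of `background`.
#' @param background character vector of all assayed genes.
#' @param term_map data.frame with columns `gene`, `term`.
#' @param adj_p_cutoff elements with adjusted p below this are flagged
#'   `significant` (default 0.01).
#' @return data.frame `term`, `overlap`, `set_size`, `term_size`,
#'   `expected`, `raw_p`, `adj_p`, `significant`, ordered by `raw_p`.
#' @export
hypergeometric_enrichment <- function(gene_set, background, term_map,
                                      adj_p_cutoff = 0.01) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  gene_set <- unique(intersect(gene_set, background))
  term_map <- term_map[term_map$gene %in% background, , drop = FALSE]
  terms <- unique(term_map$term)
  n_bg <- length(background); n_set <- length(gene_set)
  res <- lapply(terms, function(tm) {
    tg <- unique(term_map$gene[term_map$term == tm])
    k_term <- length(tg)
    k_ov <- length(intersect(tg, gene_set))
    p <- stats::phyper(k_ov - 1, k_term, n_bg - k_term, n_set,
                       lower.tail = FALSE)
    data.frame(term = tm, overlap = k_ov, set_size = n_set,
               term_size = k_term, expected = n_set * k_term / n_bg,
               raw_p = p)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    return(data.frame(term = character(), overlap = integer(),
                      set_size = integer(), term_size = integer(),
                      expected = numeric(), raw_p = numeric(),
                      adj_p = numeric(), significant = logical()))
  res$adj_p <- stats::p.adjust(res$raw_p, method = "BH")
  res$significant <- res$adj_p < adj_p_cutoff
  res[order(res$raw_p), , drop = FALSE]
}
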