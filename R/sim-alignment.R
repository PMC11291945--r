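#' Default 16-taxon topology for alignment simulation
#'
#' A balanced 16-leaf binary tree with abstract labels `sp01..sp16`
#' (focal = `sp01`) and equal branch lengths, in expected substitutions per
#' site at neutral rate 1. Biology-faithful trees are out of scope: the
#' downstream rules use sequence identity only.
#'
#' @param branch_length length of every edge (default 0.08; root-to-tip
#'   depth 0.32).
#' @return an `ape::phylo` tree.
#' @export
default_species_tree <- function(branch_length = 0.08) {
  pair <- function(a, b) paste0("(", a, ":%BL%,", b, ":%BL%)")
  tips <- sprintf("sp%02d", 1:16)
  lvl1 <- mapply(pair, tips[seq(1, 16, 2)], tips[seq(2, 16, 2)])
  lvl2 <- mapply(pair, lvl1[c(1, 3, 5, 7)], lvl1[c(2, 4, 6, 8)])
  lvl3 <- mapply(pair, lvl2[c(1, 3)], lvl2[c(2, 4)])
  nwk <- paste0(pair(lvl3[1], lvl3[2]), ";")
  nwk <- gsub("%BL%", format(branch_length), nwk)
  ape::read.tree(text = nwk)
}

# evolve one sequence down a tree; site i substitutes along an edge of
# length t with Jukes-Cantor probability 3/4 (1 - exp(-4/3 rate t))
.evolve_tree <- function(tree, root_seq, rate) {
  bases <- c("A", "C", "G", "T")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root]] <- root_seq
  ord <- reorder(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    t_edge <- ord$edge.length[k]
    p_sub <- 0.75 * (1 - exp(-4 / 3 * rate * t_edge))
    s <- seqs[[parent]]
    hit <- which(stats::runif(length(s)) < p_sub)
    if (length(hit)) {
      for (i in hit) s[i] <- sample(setdiff(bases, s[i]), 1L)
    }
    seqs[[child]] <- s
  }
  out <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(out) <- tree$tip.label
  out
}

#' Simulate a focal-referenced multi-species alignment with planted CNEs
#'
#' Evolves site-independent nucleotide sequences along a species tree
#' (uniform base exchange, Jukes-Cantor-style) and emits one MAF block per
#' locus, focal species first, plus strand. Loci alternate between neutral
#' background (rate `neutral_rate_scale`) and conserved noncoding elements
#' (rate `conserved_rate_scale`, much smaller). Two kinds of focal-lineage
#' events are planted into distinct CNEs:
#' \itemize{
#'   \item losses: the focal row is deleted over the whole element; the MAF
#'     block keeps a focal anchor line of size 0 at the deletion point so
#'     the element retains focal coordinates;
#'   \item divergences: a run of `burst_length` (>= 10) contiguous focal
#'     sites is substituted inside an otherwise conserved element.
#' }
#' A GFF3 of focal genes (with exon features) is placed in the gaps between
#' loci so the loci themselves are noncoding.
#'
#' @param tree an `ape::phylo`; default [default_species_tree()]. The focal
#'   taxon must be a leaf.
#' @param focal focal species label (default `"sp01"`).
#' @param neutral_rate_scale,conserved_rate_scale substitution-rate
#'   multipliers (defaults 1 and 0.02).
#' @param n_cnes number of conserved elements (default 30).
#' @param n_neutral number of neutral background loci (default 10).
#' @param cne_length_range element length range in bp (default 80-200).
#' @param planted_losses,planted_divergences event counts (defaults 5, 5;
#'   must sum to at most `n_cnes`; events are planted in disjoint elements).
#' @param burst_length contiguous focal-variant sites per divergence
#'   (default 12; must be >= 10).
#' @param seed integer seed.
#' @param out_dir if non-NULL, write `alignment.maf`, `genes.gff3`,
#'   `truth_lost.bed`, `truth_divergent.bed` there.
#' @return list with `segments` (list of [alignment_segment()]),
#'   `genes` (data.frame incl. exon rows), `truth` (lists
#'   `truth_lost_cnes`, `truth_divergent_cnes`, `truth_conserved_cnes`),
#'   `scaffold_lengths`, `species`, `focal`.
#' @export
simulate_species_alignment <- function(tree = default_species_tree(),
                                       focal = "sp01",
                                       neutral_rate_scale = 1,
                                       conserved_rate_scale = 0.02,
                                       n_cnes = 30L, n_neutral = 10L,
                                       cne_length_range = c(80L, 200L),
                                       planted_losses = 5L,
                                       planted_divergences = 5L,
                                       burst_length = 12L,
                                       seed = 1L, out_dir = NULL) {
  if (!focal %in% tree$tip.label) stop("focal taxon is not a leaf")
  if (burst_length < 10) stop("burst_length must be >= 10")
  if (planted_losses + planted_divergences > n_cnes)
    stop("planted events exceed n_cnes (events must be disjoint)")
  bases <- c("A", "C", "G", "T")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n_loci <- n_cnes + n_neutral
  is_cne <- rep(FALSE, n_loci)
  is_cne[sort(sample.int(n_loci, n_cnes))] <- TRUE
  lens <- ifelse(is_cne,
                 sample(cne_length_range[1]:cne_length_range[2], n_loci,
                        replace = TRUE),
                 sample(100:300, n_loci, replace = TRUE))
  gap <- 2000L
  starts <- cumsum(c(1000L, lens[-n_loci] + gap))
  chrom <- "scaf_1"
  scaffold_lengths <- stats::setNames(as.integer(starts[n_loci] +
                                                   lens[n_loci] + 5000L),
                                      chrom)

  cne_idx <- which(is_cne)
  ev <- sample(cne_idx, planted_losses + planted_divergences)
  lost_idx <- ev[seq_len(planted_losses)]
  div_idx <- ev[planted_losses + seq_len(planted_divergences)]

  segments <- vector("list", n_loci)
  truth_lost <- truth_div <- truth_cons <- list()
  for (i in seq_len(n_loci)) {
    L <- lens[i]
    rate <- if (is_cne[i]) conserved_rate_scale else neutral_rate_scale
    root <- sample(bases, L, replace = TRUE)
    rows <- .evolve_tree(tree, root, rate)
    s0 <- starts[i]; s1 <- s0 + L
    if (i %in% div_idx) {
      off <- sample.int(L - burst_length + 1L, 1L)
      cols <- off:(off + burst_length - 1L)
      for (j in cols)
        rows[focal, j] <- sample(setdiff(bases, rows[focal, j]), 1L)
      truth_div[[length(truth_div) + 1L]] <- data.frame(
        chrom = chrom, start = s0, end = s1,
        burst_start = s0 + off - 1L, burst_len = burst_length)
      segments[[i]] <- alignment_segment(rows, chrom, s0, s1, focal)
    } else if (i %in% lost_idx) {
      rows[focal, ] <- "-"
      truth_lost[[length(truth_lost) + 1L]] <- data.frame(
        chrom = chrom, start = s0, end = s0)
      segments[[i]] <- alignment_segment(rows, chrom, s0, s0, focal)
    } else {
      if (is_cne[i])
        truth_cons[[length(truth_cons) + 1L]] <- data.frame(
          chrom = chrom, start = s0, end = s1)
      segments[[i]] <- alignment_segment(rows, chrom, s0, s1, focal)
    }
  }

  # genes in the inter-locus gaps (so loci are noncoding); one exon each
  gene_rows <- list()
  for (i in seq_len(n_loci - 1L)) {
    gs <- starts[i] + lens[i] + 500L
    ge <- gs + 800L
    gid <- sprintf("gene%03d", i)
    strand <- if (i %% 2 == 0) "-" else "+"
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      chrom = chrom, start = gs, end = ge, strand = strand,
      gene_id = c(gid, paste0(gid, ".e1")), type = c("gene", "exon"))
  }
  genes <- do.call(rbind, gene_rows)

  bindrows <- function(x) if (length(x)) do.call(rbind, x) else
    data.frame(chrom = character(), start = integer(), end = integer())
  truth <- list(truth_lost_cnes = bindrows(truth_lost),
                truth_divergent_cnes = bindrows(truth_div),
                truth_conserved_cnes = bindrows(truth_cons))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_maf(segments, file.path(out_dir, "alignment.maf"),
              scaffold_lengths)
    write_gff3(genes, file.path(out_dir, "genes.gff3"))
    write_bed(truth$truth_lost_cnes, file.path(out_dir, "truth_lost.bed"))
    write_bed(truth$truth_divergent_cnes,
              file.path(out_dir, "truth_divergent.bed"))
  }
  list(segments = segments, genes = genes, truth = truth,
       scaffold_lengths = scaffold_lengths, species = tree$tip.label,
       focal = focal)
}
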