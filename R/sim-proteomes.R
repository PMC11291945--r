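#' Simulate one-to-one ortholog proteomes with planted focal substitutions
#'
#' Generates a focal proteome of random amino-acid sequences and, for each
#' non-focal species, a low-divergence ortholog of every gene (per-site
#' substitution probability `background_divergence`). At each planted site
#' the 15 non-focal species are forced to share one residue while the focal
#' species carries a different one; the 10 residues flanking each side keep
#' the background (high) conservation, so the site satisfies the
#' conserved-flank rule of the downstream scan. Planted sites avoid the
#' first and last 10 residues of a protein.
#'
#' @param n_species total species including the focal one (default 16).
#' @param n_genes genes per proteome (default 50).
#' @param planted_sites number of focal-specific substitutions to plant
#'   (default 10), at most one per gene.
#' @param background_divergence per-site substitution probability in
#'   non-focal orthologs (default 0: noiseless).
#' @param protein_length_range residues (default 120-240).
#' @param seed integer seed; same seed gives identical FASTA output.
#' @param out_dir if non-NULL, write one `<species>.faa` per species plus
#'   `truth_substitutions.tsv` there.
#' @return list with `proteomes` (named list of named character vectors;
#'   first element is the focal species `sp01`), `truth` (data.frame
#'   `gene`, `column`, `focal_residue`, `consensus_residue`), `species`,
#'   `focal`.
#' @export
simulate_ortholog_proteomes <- function(n_species = 16L, n_genes = 50L,
                                        planted_sites = 10L,
                                        background_divergence = 0,
                                        protein_length_range = c(120L, 240L),
                                        seed = 1L, out_dir = NULL) {
  if (planted_sites > n_genes)
    stop("at most one planted site per gene")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  species <- sprintf("sp%02d", seq_len(n_species))
  focal <- species[1]
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  lens <- sample(protein_length_range[1]:protein_length_range[2], n_genes,
                 replace = TRUE)
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  focal_mat <- lapply(lens, function(L) sample(aa, L, replace = TRUE))
  names(focal_mat) <- gene_ids

  planted_genes <- sample(gene_ids, planted_sites)
  truth <- data.frame(gene = character(), column = integer(),
                      focal_residue = character(),
                      consensus_residue = character())
  mut <- function(res) sample(setdiff(aa, res), 1L)
  for (gid in planted_genes) {
    L <- length(focal_mat[[gid]])
    if (L < 22) stop("protein too short to host an interior planted site")
    col <- sample(11:(L - 10), 1L)
    cons <- focal_mat[[gid]][col]           # non-focal consensus
    focal_res <- mut(cons)
    focal_mat[[gid]][col] <- focal_res
    truth <- rbind(truth, data.frame(gene = gid, column = col,
                                     focal_residue = focal_res,
                                     consensus_residue = cons))
  }

  proteomes <- stats::setNames(vector("list", n_species), species)
  proteomes[[focal]] <- vapply(focal_mat, paste, "", collapse = "")
  for (sp in species[-1]) {
    seqs <- character(n_genes)
    for (gi in seq_len(n_genes)) {
      gid <- gene_ids[gi]
      s <- focal_mat[[gid]]
      planted_col <- truth$column[truth$gene == gid]
      if (length(planted_col))                 # restore the consensus residue
        s[planted_col] <- truth$consensus_residue[truth$gene == gid]
      if (background_divergence > 0) {
        hit <- which(stats::runif(length(s)) < background_divergence)
        hit <- setdiff(hit, planted_col)       # keep the planted column clean
        for (i in hit) s[i] <- mut(s[i])
      }
      seqs[gi] <- paste(s, collapse = "")
    }
    names(seqs) <- paste0(sp, "_", gene_ids)
    proteomes[[sp]] <- seqs
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (sp in species)
      write_proteome(proteomes[[sp]], file.path(out_dir,
                                                paste0(sp, ".faa")))
    utils::write.table(truth,
                       file.path(out_dir, "truth_substitutions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(proteomes = proteomes, truth = truth, species = species,
       focal = focal)
}
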