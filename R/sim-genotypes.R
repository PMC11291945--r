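#' Simulate two-population genotypes under the Balding-Nichols model
#'
#' Generates diploid biallelic SNP genotypes for two populations (labelled
#' wild and domestic) with a controlled level of differentiation and,
#' optionally, planted low-diversity sweep windows in the target population.
#'
#' Per SNP an ancestral frequency p is drawn uniformly on `[0.05, 0.95]`;
#' each population's frequency is then drawn from
#' `Beta(p (1-F)/F, (1-p) (1-F)/F)` with `F = target_fst` (the
#' Balding-Nichols model, whose between-population frequency variance is
#' `F p (1-p)`, matching the Weir-Cockerham FST expectation). `target_fst =
#' 0` short-circuits to identical population frequencies. Genotypes are
#' binomial(2, freq) draws. Inside each sweep window the target population's
#' frequency is moved toward the nearest boundary by solving
#' `2 p' (1-p') = diversity_reduction * 2 p (1-p)` in closed form, so the
#' window's expected heterozygosity is multiplied exactly by
#' `diversity_reduction` (which also elevates differentiation there).
#'
#' @param n_samples_per_pop diploid samples per population (default 20).
#' @param n_scaffolds,scaffold_length genome layout (default 4 x 5 Mb).
#' @param snp_density expected variant sites per bp (default 0.001, i.e.
#'   20,000 SNPs on the default genome).
#' @param target_fst Balding-Nichols differentiation in `[0, 0.99]`.
#' @param sweep_windows `NULL`, or data.frame `chrom`, `start`, `end`
#'   (0-based half-open), `diversity_reduction` in `(0, 1]`.
#' @param target_pop population receiving the sweeps (default
#'   `"domestic"`).
#' @param seed integer seed; the same seed gives byte-identical outputs.
#' @param out_dir if non-NULL, write `genotypes.vcf`, `popmap.tsv` and
#'   `truth_sweeps.bed` there.
#' @return list with `genotypes` (a [genotype_matrix()] carrying
#'   `scaffold_lengths`), `popmap` (data.frame), and `truth` (list with
#'   `truth_sweeps`).
#' @export
simulate_population_genotypes <- function(n_samples_per_pop = 20L,
                                          n_scaffolds = 4L,
                                          scaffold_length = 5e6,
                                          snp_density = 0.001,
                                          target_fst = 0.1,
                                          sweep_windows = NULL,
                                          target_pop = "domestic",
                                          seed = 1L, out_dir = NULL) {
  if (n_samples_per_pop < 1 || n_scaffolds < 1 || scaffold_length < 1)
    stop("counts must be positive")
  if (target_fst < 0 || target_fst > 0.99)
    stop("target_fst must lie in [0, 0.99]")
  scaffold_lengths <- stats::setNames(rep(as.integer(scaffold_length),
                                          n_scaffolds),
                                      paste0("scaf_", seq_len(n_scaffolds)))
  if (!is.null(sweep_windows)) {
    for (i in seq_len(nrow(sweep_windows))) {
      sc <- sweep_windows$chrom[i]
      if (!sc %in% names(scaffold_lengths) ||
          sweep_windows$start[i] < 0 ||
          sweep_windows$end[i] > scaffold_lengths[[sc]])
        stop("sweep window outside scaffold bounds: row ", i)
    }
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n_sites_per <- round(scaffold_length * snp_density)
  chrom <- rep(names(scaffold_lengths), each = n_sites_per)
  pos <- unlist(lapply(seq_len(n_scaffolds), function(i)
    sort(sample.int(scaffold_length, n_sites_per))))
  n_sites <- length(pos)

  p_anc <- stats::runif(n_sites, 0.05, 0.95)
  draw_pop <- function() {
    if (target_fst == 0) return(p_anc)
    a <- p_anc * (1 - target_fst) / target_fst
    b <- (1 - p_anc) * (1 - target_fst) / target_fst
    stats::rbeta(n_sites, a, b)
  }
  p_pop <- list(wild = draw_pop(), domestic = draw_pop())

  if (!is.null(sweep_windows)) {
    pt <- p_pop[[target_pop]]
    for (i in seq_len(nrow(sweep_windows))) {
      idx <- which(chrom == sweep_windows$chrom[i] &
                     pos > sweep_windows$start[i] &
                     pos <= sweep_windows$end[i])
      cc <- sweep_windows$diversity_reduction[i]
      p <- pt[idx]
      disc <- sqrt(pmax(1 - 4 * cc * p * (1 - p), 0))
      pt[idx] <- ifelse(p <= 0.5, (1 - disc) / 2, (1 + disc) / 2)
    }
    p_pop[[target_pop]] <- pt
  }

  geno <- matrix(NA_integer_, n_sites, 2L * n_samples_per_pop)
  for (k in seq_len(n_samples_per_pop)) {
    geno[, k] <- stats::rbinom(n_sites, 2L, p_pop$wild)
    geno[, n_samples_per_pop + k] <- stats::rbinom(n_sites, 2L,
                                                   p_pop$domestic)
  }
  samples <- c(sprintf("wild_%02d", seq_len(n_samples_per_pop)),
               sprintf("dom_%02d", seq_len(n_samples_per_pop)))
  colnames(geno) <- samples
  ref_alt <- c("A", "C", "G", "T")
  ref <- sample(ref_alt, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(ref_alt, r), 1L), "")
  info <- data.frame(QD = round(stats::runif(n_sites, 20, 35), 2),
                     FS = round(stats::rexp(n_sites, 1), 3),
                     MQ = round(stats::runif(n_sites, 55, 60), 2),
                     MQRankSum = round(stats::rnorm(n_sites, 0, 1), 3),
                     ReadPosRankSum = round(stats::rnorm(n_sites, 0, 1), 3))
  g <- genotype_matrix(geno, chrom, pos, ref, alt, info = info)
  attr(g, "scaffold_lengths") <- scaffold_lengths

  popmap <- data.frame(sample = samples,
                       population = rep(c("wild", "domestic"),
                                        each = n_samples_per_pop),
                       status = rep(c("wild", "domestic"),
                                    each = n_samples_per_pop))
  truth <- list(truth_sweeps = if (is.null(sweep_windows))
    data.frame(chrom = character(), start = integer(), end = integer(),
               diversity_reduction = numeric()) else sweep_windows)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(g, file.path(out_dir, "genotypes.vcf"), scaffold_lengths)
    write_popmap(popmap, file.path(out_dir, "popmap.tsv"))
    write_bed(truth$truth_sweeps, file.path(out_dir, "truth_sweeps.bed"))
  }
  list(genotypes = g, popmap = popmap, truth = truth,
       scaffold_lengths = scaffold_lengths)
}
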