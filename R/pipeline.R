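.default_config <- function() {
  list(
    seed = 1L,
    out_dir = "domestiscan_out",
    simulate = list(
      genotypes = list(n_samples_per_pop = 10L, n_scaffolds = 2L,
                       scaffold_length = 2e6, snp_density = 0.001,
                       target_fst = 0.1, n_sweep_windows = 4L,
                       diversity_reduction = 0.2),
      alignment = list(n_cnes = 20L, n_neutral = 8L, planted_losses = 4L,
                       planted_divergences = 4L, burst_length = 12L,
                       conserved_rate_scale = 0),
      proteomes = list(n_genes = 12L, planted_sites = 5L,
                       background_divergence = 0)),
    popstats = list(window_kb = 50, step_kb = 10, max_ld_kb = 501,
                    ld_bin_kb = 10, ld_max_sites = 300L),
    sweep = list(alpha = 0.05, iterations = 1000L, min_pi = 1e-8,
                 min_sites = 3L, orientation = "ref_over_target"),
    cne = list(min_similarity = 0.8, min_len = 50L, min_contiguous = 10L,
               min_all_conservation = 0.8, min_column_support = 0.8,
               max_focal_gap = 0.8),
    aasub = list(flank = 10L, flank_min_sim = 0.6, flank_mode = "joint"),
    enrich = list(adj_p_cutoff = 0.01))
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration (or accepts a list), fills unset values from
#' the package defaults, and rejects unknown keys at the top and stage
#' level so typos fail before any compute.
#'
#' @param config path to a YAML file, or a (possibly partial) named list.
#' @return the resolved configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- .default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(config)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      bad <- setdiff(names(config[[k]]), names(def[[k]]))
      if (length(bad) && k != "simulate")
        stop("unknown config key(s) under '", k, "': ",
             paste(bad, collapse = ", "))
    }
  }
  utils::modifyList(def, config)
}

# windowed pi for a sample subset, shared tiling
.comparison_regions <- function(g, windows, wild, dom, cfg_sweep) {
  pi_w <- windowed_pi(g, wild, windows)
  pi_d <- windowed_pi(g, dom, windows)
  popmap <- data.frame(sample = c(wild, dom),
                       population = rep(c("wild", "domestic"),
                                        c(length(wild), length(dom))))
  fst <- windowed_wc_fst(g, popmap, windows)
  lnr <- ln_diversity_ratio(pi_d, pi_w, min_pi = cfg_sweep$min_pi,
                            min_sites = cfg_sweep$min_sites,
                            orientation = cfg_sweep$orientation)
  ok_fst <- fst$fst[is.finite(fst$fst)]
  th_f <- empirical_z_thresholds(ok_fst, cfg_sweep$alpha)
  th_l <- empirical_z_thresholds(lnr$ln_ratio, cfg_sweep$alpha)
  win <- call_selected_windows(fst, lnr, th_f, th_l)
  list(windows = win,
       regions = merge_windows_to_regions(win),
       thresholds = c(fst = th_f, ln_ratio = th_l),
       fst = fst, pi_wild = pi_w, pi_domestic = pi_d, ln_ratio = lnr)
}

#' Run the full synthetic-fixture pipeline
#'
#' Generates the synthetic inputs (VCF + population map, MAF + GFF3,
#' proteome FASTAs) from the configured seeds, round-trips them through the
#' package readers, and executes every analysis stage in order: variant
#' hard-filtering; windowed pi / FST / per-sample statistics; sweep-window
#' calling (three wild-vs-domestic sample-subset comparisons), region
#' merging, triple intersection and the Monte Carlo overlap test; CNE
#' discovery with lost/divergent classification, nearest-gene assignment
#' and term enrichment; and the ortholog substitution scan. All tables are
#' written under `config$out_dir` together with the resolved configuration
#' and a `summary.json` carrying the configuration hash; a rerun with the
#' same configuration is byte-identical.
#'
#' @param config path to a YAML file or a partial configuration list
#'   (see [pipeline_config()]).
#' @return invisibly, a list with the per-stage results and the summary.
#' @export
run_full_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out, "config_resolved.yaml")
  yaml::write_yaml(cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  tsv <- function(df, name) utils::write.table(
    df, file.path(out, name), sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- genotype simulation + filtering -------------------------------------
  sg <- cfg$simulate$genotypes
  win_bp <- cfg$popstats$window_kb * 1000
  sweep_truth <- NULL
  if (sg$n_sweep_windows > 0) {
    starts <- seq(2L, by = 5L, length.out = sg$n_sweep_windows) * win_bp
    sweep_truth <- data.frame(
      chrom = paste0("scaf_", rep(seq_len(sg$n_scaffolds),
                                  length.out = sg$n_sweep_windows)),
      start = starts %% (sg$scaffold_length - win_bp),
      end = starts %% (sg$scaffold_length - win_bp) + win_bp,
      diversity_reduction = sg$diversity_reduction)
  }
  sim <- simulate_population_genotypes(
    n_samples_per_pop = sg$n_samples_per_pop, n_scaffolds = sg$n_scaffolds,
    scaffold_length = sg$scaffold_length, snp_density = sg$snp_density,
    target_fst = sg$target_fst, sweep_windows = sweep_truth,
    seed = cfg$seed, out_dir = out)
  g <- read_vcf(file.path(out, "genotypes.vcf"), verbose = FALSE)
  popmap <- read_popmap(file.path(out, "popmap.tsv"))
  g <- filter_variants(g)
  scaff <- attr(g, "scaffold_lengths")

  ## -- windowed statistics + per-sample statistics -------------------------
  windows <- make_windows(scaff, size = win_bp,
                          step = cfg$popstats$step_kb * 1000)
  wild <- popmap$sample[popmap$population == "wild"]
  dom <- popmap$sample[popmap$population == "domestic"]
  half <- function(x, first) if (first) x[seq_len(ceiling(length(x) / 2))]
  else x[-seq_len(ceiling(length(x) / 2))]
  comparisons <- list(
    all = list(wild = wild, dom = dom),
    subset_a = list(wild = half(wild, TRUE), dom = half(dom, TRUE)),
    subset_b = list(wild = half(wild, FALSE), dom = half(dom, FALSE)))
  comp_res <- lapply(comparisons, function(cc)
    .comparison_regions(g, windows, cc$wild, cc$dom, cfg$sweep))
  for (nm in names(comp_res)) {
    tsv(comp_res[[nm]]$fst, paste0("fst_", nm, ".tsv"))
    tsv(comp_res[[nm]]$ln_ratio, paste0("ln_ratio_", nm, ".tsv"))
    reg <- comp_res[[nm]]$regions
    tsv(reg, paste0("regions_", nm, ".tsv"))
  }
  tsv(comp_res$all$pi_wild, "pi_wild.tsv")
  tsv(comp_res$all$pi_domestic, "pi_domestic.tsv")

  het <- vapply(g$samples, function(s) sample_heterozygosity(g, s), 0)
  fcoef <- vapply(g$samples, function(s) inbreeding_coefficient(g, s), 0)
  tsv(data.frame(sample = g$samples, heterozygosity = het,
                 inbreeding_f = fcoef), "sample_stats.tsv")
  roh <- detect_roh(g, g$samples[1])
  tsv(roh, "roh_sample1.tsv")
  ld_g <- subset_genotypes(g, sites = seq_len(min(cfg$popstats$ld_max_sites,
                                                  nrow(g$geno))))
  ld <- ld_decay(ld_g, max_dist_kb = cfg$popstats$max_ld_kb,
                 bin_kb = cfg$popstats$ld_bin_kb)
  tsv(ld$bins, "ld_bins.tsv")

  ## -- sweep region intersection + Monte Carlo -----------------------------
  region_sets <- lapply(comp_res, `[[`, "regions")
  shared <- intersect_region_sets(region_sets)
  genes_gt <- NULL
  mc <- monte_carlo_overlap_pvalue(region_sets, scaff,
                                   n_iter = cfg$sweep$iterations,
                                   seed = cfg$seed + 1L)
  tsv(shared, "regions_shared.tsv")
  write_bed(cbind(shared, name = rep("shared",
                                     nrow(shared))), file.path(
                                       out, "regions_shared.bed"))

  ## -- CNE discovery -------------------------------------------------------
  sa <- cfg$simulate$alignment
  aln <- simulate_species_alignment(
    n_cnes = sa$n_cnes, n_neutral = sa$n_neutral,
    planted_losses = sa$planted_losses,
    planted_divergences = sa$planted_divergences,
    burst_length = sa$burst_length,
    conserved_rate_scale = sa$conserved_rate_scale,
    seed = cfg$seed + 2L, out_dir = out)
  segs <- read_maf(file.path(out, "alignment.maf"))
  exons <- read_gff3(file.path(out, "genes.gff3"), feature = "exon")
  genes <- read_gff3(file.path(out, "genes.gff3"), feature = "gene")
  nc <- extract_noncoding_segments(segs, exons, min_len = cfg$cne$min_len)
  cand <- find_conserved_elements(nc, aln$species, aln$focal,
                                  min_similarity = cfg$cne$min_similarity,
                                  min_len = cfg$cne$min_len)
  lost <- classify_lost(cand, nc, max_focal_gap = cfg$cne$max_focal_gap)
  divg <- classify_divergent(
    cand, nc, aln$species, aln$focal,
    min_contiguous = cfg$cne$min_contiguous,
    min_all_conservation = cfg$cne$min_all_conservation,
    min_column_support = cfg$cne$min_column_support)
  cne_all <- rbind(cand[, c("chrom", "start", "end", "class")],
                   lost[, c("chrom", "start", "end", "class")],
                   divg[, c("chrom", "start", "end", "class")])
  tsv(cne_all, "cne_table.tsv")
  write_bed(cbind(cne_all, name = cne_all$class),
            file.path(out, "cne.bed"))
  assign_div <- if (nrow(divg)) nearest_gene(divg, genes) else NULL
  if (!is.null(assign_div)) tsv(assign_div, "cne_divergent_genes.tsv")

  ## term enrichment of divergent-CNE neighbour genes against a synthetic
  ## term map: one term concentrates the neighbours, others are random
  enr <- NULL
  if (!is.null(assign_div) && nrow(assign_div)) {
    background <- sort(unique(genes$gene_id))
    target_genes <- unique(assign_div$gene_id[assign_div$gene_id != "none"])
    set.seed(cfg$seed + 3L)
    other <- setdiff(background, target_genes)
    term_map <- rbind(
      data.frame(gene = target_genes, term = "T_target"),
      data.frame(gene = sample(background,
                               min(8L, length(background))), term = "T_a"),
      data.frame(gene = sample(background,
                               min(12L, length(background))), term = "T_b"))
    enr <- hypergeometric_enrichment(target_genes, background, term_map,
                                     adj_p_cutoff = cfg$enrich$adj_p_cutoff)
    tsv(enr, "cne_enrichment.tsv")
  }

  ## -- ortholog substitution scan ------------------------------------------
  sp <- cfg$simulate$proteomes
  prot <- simulate_ortholog_proteomes(
    n_genes = sp$n_genes, planted_sites = sp$planted_sites,
    background_divergence = sp$background_divergence,
    seed = cfg$seed + 4L, out_dir = out)
  proteomes <- lapply(stats::setNames(prot$species, prot$species),
                      function(s) read_proteome(file.path(
                        out, paste0(s, ".faa"))))
  groups <- build_ortholog_groups(proteomes[[prot$focal]],
                                  proteomes[setdiff(prot$species,
                                                    prot$focal)])
  sites <- scan_all_groups(groups, flank = cfg$aasub$flank,
                           flank_min_sim = cfg$aasub$flank_min_sim,
                           flank_mode = cfg$aasub$flank_mode)
  tsv(sites, "aa_substitutions.tsv")
  sub_genes <- genes_with_substitutions(sites)

  ## -- summary --------------------------------------------------------------
  summary <- list(
    config_hash = cfg_hash,
    seed = cfg$seed,
    n_snps_after_filter = nrow(g$geno),
    n_regions = vapply(region_sets, nrow, 0L),
    n_shared_regions = nrow(shared),
    mc_overlap_p = mc$p_value,
    n_cne_candidates = nrow(cand),
    n_cne_lost = nrow(lost),
    n_cne_divergent = nrow(divg),
    n_substitution_sites = nrow(sites),
    n_substitution_genes = sub_genes$count)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(config = cfg, genotypes = g, comparisons = comp_res,
                 shared_regions = shared, mc = mc, cne = list(
                   candidates = cand, lost = lost, divergent = divg,
                   enrichment = enr), substitutions = sites,
                 truth = list(sweeps = sim$truth$truth_sweeps,
                              cne = aln$truth, substitutions = prot$truth),
                 summary = summary))
}
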