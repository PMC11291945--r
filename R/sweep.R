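#' Windowed ln diversity ratio
#'
#' Per window, the natural log of the ratio of nucleotide diversity between a
#' reference and a putatively selected target population. With the default
#' orientation `"ref_over_target"` the value is `ln(pi_reference /
#' pi_target)`, so positive values flag reduced diversity in the target
#' (domestic) group and positive thresholds select sweep candidates. The
#' orientation is a flag because published sign conventions for this ratio
#' vary. Windows where either pi falls below `min_pi` or where either
#' population has fewer than `min_sites` variant sites are dropped and listed
#' in the `dropped` attribute.
#'
#' @param pi_target,pi_reference data.frames from [windowed_pi()] on the same
#'   tiling (target = putatively selected population).
#' @param min_pi smallest pi accepted in either population (> 0 required to
#'   take the log).
#' @param min_sites minimum variant sites per window in each population.
#' @param orientation `"ref_over_target"` (default) or `"target_over_ref"`.
#' @return data.frame `chrom`, `start`, `end`, `ln_ratio`, `n_sites`;
#'   attribute `dropped` holds the excluded windows.
#' @export
ln_diversity_ratio <- function(pi_target, pi_reference, min_pi = 1e-8,
                               min_sites = 3L,
                               orientation = c("ref_over_target",
                                               "target_over_ref")) {
  orientation <- match.arg(orientation)
  if (nrow(pi_target) != nrow(pi_reference) ||
      !all(pi_target$chrom == pi_reference$chrom &
           pi_target$start == pi_reference$start &
           pi_target$end == pi_reference$end))
    stop("window tilings differ between target and reference")
  keep <- pi_target$pi >= min_pi & pi_reference$pi >= min_pi &
    pi_target$n_sites >= min_sites & pi_reference$n_sites >= min_sites
  ratio <- if (orientation == "ref_over_target")
    log(pi_reference$pi / pi_target$pi) else
      log(pi_target$pi / pi_reference$pi)
  out <- data.frame(chrom = pi_target$chrom, start = pi_target$start,
                    end = pi_target$end, ln_ratio = ratio,
                    n_sites = pmin(pi_target$n_sites, pi_reference$n_sites))
  dropped <- out[!keep, , drop = FALSE]
  out <- out[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Empirical one-tailed Z threshold
#'
#' Threshold above which a value lies in the upper `alpha` tail of a normal
#' fitted to the empirical window distribution:
#' `mean + qnorm(1 - alpha) * sd`.
#'
#' @param values finite statistic values (>= 30 required).
#' @param alpha upper tail probability (default 0.05, z = 1.6449).
#' @return the threshold.
#' @export
empirical_z_thresholds <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 30) stop("need >= 30 finite values")
  s <- stats::sd(values)
  if (s == 0) stop("zero variance: threshold undefined")
  mean(values) + stats::qnorm(1 - alpha) * s
}

#' Select windows jointly exceeding FST and ln-ratio thresholds
#'
#' A window is called when its FST strictly exceeds `fst_threshold` AND its
#' ln diversity ratio strictly exceeds `ln_ratio_threshold` — the joint rule
#' used to flag candidate sweep windows.
#'
#' @param fst_stats data.frame from [windowed_wc_fst()].
#' @param lnratio_stats data.frame from [ln_diversity_ratio()].
#' @param fst_threshold,ln_ratio_threshold thresholds (e.g. from
#'   [empirical_z_thresholds()], or taken directly from a prior analysis).
#' @return data.frame of selected windows with both statistics.
#' @export
call_selected_windows <- function(fst_stats, lnratio_stats, fst_threshold,
                                  ln_ratio_threshold) {
  key_f <- paste(fst_stats$chrom, fst_stats$start, fst_stats$end)
  key_l <- paste(lnratio_stats$chrom, lnratio_stats$start, lnratio_stats$end)
  m <- match(key_l, key_f)
  if (anyNA(m)) stop("ln-ratio windows not a subset of the FST tiling")
  out <- data.frame(chrom = lnratio_stats$chrom, start = lnratio_stats$start,
                    end = lnratio_stats$end, fst = fst_stats$fst[m],
                    ln_ratio = lnratio_stats$ln_ratio)
  sel <- !is.na(out$fst) & is.finite(out$ln_ratio) &
    out$fst > fst_threshold & out$ln_ratio > ln_ratio_threshold
  out[sel, , drop = FALSE]
}

#' Merge selected windows into candidate regions
#'
#' Overlapping or book-ended windows on one scaffold are merged into maximal
#' regions; each region records its window count and maximal statistics.
#'
#' @param windows data.frame from [call_selected_windows()] (columns `chrom`,
#'   `start`, `end`, optionally `fst`, `ln_ratio`).
#' @param max_gap merge windows whose gap is at most this many bp (default 0:
#'   only overlapping/adjacent windows merge).
#' @param label comparison label attached to the output.
#' @return data.frame `chrom`, `start`, `end`, `comparison`, `n_windows`,
#'   `max_fst`, `max_ln_ratio`.
#' @export
merge_windows_to_regions <- function(windows, max_gap = 0L, label = NA) {
  reg <- merge_intervals(windows, max_gap = max_gap)
  if (nrow(reg) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), comparison = character(),
                      n_windows = integer(), max_fst = numeric(),
                      max_ln_ratio = numeric()))
  reg$comparison <- label
  reg$n_windows <- NA_integer_
  reg$max_fst <- NA_real_
  reg$max_ln_ratio <- NA_real_
  for (i in seq_len(nrow(reg))) {
    inr <- windows$chrom == reg$chrom[i] & windows$start < reg$end[i] &
      windows$end > reg$start[i]
    reg$n_windows[i] <- sum(inr)
    if ("fst" %in% names(windows)) reg$max_fst[i] <- max(windows$fst[inr])
    if ("ln_ratio" %in% names(windows))
      reg$max_ln_ratio[i] <- max(windows$ln_ratio[inr])
  }
  reg
}

#' Intersect several region sets
#'
#' Maximal intervals covered by at least one region from every input set —
#' the shared signal across independent wild-vs-domestic comparisons.
#'
#' @param sets list of >= 2 region data.frames (`chrom`, `start`, `end`).
#' @return data.frame of the shared intervals.
#' @export
intersect_region_sets <- function(sets) {
  if (length(sets) < 2) stop("need at least two region sets")
  merged <- lapply(sets, merge_intervals)
  Reduce(intersect_two, merged)
}

#' Monte Carlo significance of a multi-set region overlap
#'
#' Tests whether the observed number of intervals shared by all region sets
#' exceeds what random placement would produce. Each iteration independently
#' re-places every region of every set: a scaffold is chosen with probability
#' proportional to the number of valid start positions it offers
#' (scaffold length - region length + 1) and the start drawn uniformly among
#' them; region lengths and counts are preserved, within-set overlap after
#' placement is allowed. The statistic is the count of intervals in the
#' all-sets intersection, and the p-value uses the add-one estimator
#' `p = (1 + #{iterations >= observed}) / (1 + n_iter)` so it is never zero.
#'
#' @param sets list of region data.frames (`chrom`, `start`, `end`).
#' @param scaffold_lengths named vector of scaffold lengths (bp).
#' @param n_iter Monte Carlo iterations (default 10000).
#' @param seed integer seed.
#' @return list with `observed_overlap_count`, `n_iterations`, `p_value`,
#'   `seed`, and `null_counts` (the simulated statistic per iteration).
#' @export
monte_carlo_overlap_pvalue <- function(sets, scaffold_lengths,
                                       n_iter = 10000L, seed = 1L) {
  observed <- nrow(intersect_region_sets(sets))
  lens <- lapply(sets, function(s) s$end - s$start)
  sc_names <- names(scaffold_lengths)
  sc_len <- as.numeric(scaffold_lengths)
  for (l in unlist(lens))
    if (all(sc_len < l)) stop("region of length ", l, " fits on no scaffold")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  place <- function(lengths) {
    k <- length(lengths)
    chrom <- character(k); start <- integer(k)
    for (i in seq_len(k)) {
      slots <- pmax(sc_len - lengths[i] + 1, 0)
      sc <- sample.int(length(sc_len), 1L, prob = slots)
      chrom[i] <- sc_names[sc]
      start[i] <- sample.int(slots[sc], 1L) - 1L
    }
    data.frame(chrom = chrom, start = start, end = start + lengths)
  }
  null_counts <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    rand_sets <- lapply(lens, place)
    null_counts[it] <- nrow(intersect_region_sets(rand_sets))
  }
  p <- (1 + sum(null_counts >= observed)) / (1 + n_iter)
  list(observed_overlap_count = observed, n_iterations = n_iter,
       p_value = p, seed = seed, null_counts = null_counts)
}

#' Attach overlapping gene ids to regions
#'
#' @param regions data.frame (`chrom`, `start`, `end`, 0-based half-open).
#' @param genes data.frame of gene spans as returned by [read_gff3()]
#'   (columns `chrom`, `start`, `end`, `gene_id`; 0-based half-open).
#' @return `regions` with a `genes` column: comma-separated ids of genes
#'   whose span intersects the region, or `"none"`.
#' @export
annotate_regions_with_genes <- function(regions, genes) {
  regions$genes <- vapply(seq_len(nrow(regions)), function(i) {
    hit <- genes$chrom == regions$chrom[i] &
      genes$start < regions$end[i] & genes$end > regions$start[i]
    if (!any(hit)) "none" else paste(genes$gene_id[hit], collapse = ",")
  }, character(1))
  regions
}
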