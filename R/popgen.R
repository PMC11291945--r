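#' Hard-filter variants and enforce a minimum call rate
#'
#' Applies the standard GATK-style hard filters for SNPs: a record is removed
#' when QD < 2.0, FS > 60.0, MQ < 40.0, MQRankSum < -12.5 or
#' ReadPosRankSum < -8.0 (a missing INFO key passes), and additionally when
#' its genotype call rate falls below `min_call_rate` (default: genotyped in
#' at least 90% of samples).
#'
#' @param g a `genotype_matrix` whose `info` slot carries the INFO fields.
#' @param thresholds named list overriding any of `qd_min`, `fs_max`,
#'   `mq_min`, `mqranksum_min`, `readposranksum_min`.
#' @param min_call_rate minimum fraction of samples with a genotype call.
#' @return The filtered `genotype_matrix`, with attribute `n_removed`.
#' @export
filter_variants <- function(g, thresholds = list(), min_call_rate = 0.9) {
  stopifnot(inherits(g, "genotype_matrix"))
  th <- utils::modifyList(list(qd_min = 2.0, fs_max = 60.0, mq_min = 40.0,
                               mqranksum_min = -12.5,
                               readposranksum_min = -8.0),
                          thresholds)
  n <- nrow(g$geno)
  fail <- rep(FALSE, n)
  info <- g$info
  chk <- function(x, bad) !is.na(x) & bad(x)
  if (!is.null(info)) {
    if (!is.null(info$QD)) fail <- fail | chk(info$QD, function(x) x < th$qd_min)
    if (!is.null(info$FS)) fail <- fail | chk(info$FS, function(x) x > th$fs_max)
    if (!is.null(info$MQ)) fail <- fail | chk(info$MQ, function(x) x < th$mq_min)
    if (!is.null(info$MQRankSum))
      fail <- fail | chk(info$MQRankSum, function(x) x < th$mqranksum_min)
    if (!is.null(info$ReadPosRankSum))
      fail <- fail | chk(info$ReadPosRankSum,
                         function(x) x < th$readposranksum_min)
  }
  call_rate <- rowMeans(!is.na(g$geno))
  fail <- fail | call_rate < min_call_rate
  out <- subset_genotypes(g, sites = !fail)
  attr(out, "scaffold_lengths") <- attr(g, "scaffold_lengths")
  attr(out, "n_removed") <- sum(fail)
  out
}

#' Tile scaffolds into sliding windows
#'
#' Fixed tiling from the scaffold origin, 0-based half-open. Terminal windows
#' shorter than `size` are kept; their statistics are normalised by actual
#' span.
#'
#' @param scaffold_lengths named integer vector of scaffold lengths (bp).
#' @param size window size in bp (default 50 kb).
#' @param step step in bp (default 10 kb).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
make_windows <- function(scaffold_lengths, size = 50000L, step = 10000L) {
  stopifnot(size > 0, step > 0, !is.null(names(scaffold_lengths)))
  out <- lapply(names(scaffold_lengths), function(sc) {
    len <- scaffold_lengths[[sc]]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    data.frame(chrom = sc, start = as.integer(starts),
               end = as.integer(pmin(starts + size, len)))
  })
  do.call(rbind, out)
}

# indices of sites falling in a 0-based half-open window (1-based positions)
.sites_in_window <- function(g, chrom, start, end) {
  which(g$chrom == chrom & g$pos > start & g$pos <= end)
}

#' Windowed nucleotide diversity (pi)
#'
#' Per site, pi = 2 j (n - j) / (n (n - 1)) where j is the alternate-allele
#' count among the n non-missing alleles of the chosen samples — the mean
#' number of pairwise differences per site. Window pi is the sum of site pi
#' divided by the window length in bp, i.e. positions without a variant record
#' are treated as invariant (the convention of windowed-diversity tools).
#'
#' @param g a `genotype_matrix`.
#' @param samples sample ids to include (default all).
#' @param windows data.frame from [make_windows()].
#' @return data.frame `chrom`, `start`, `end`, `pi`, `n_sites` (variant sites
#'   with >= 2 non-missing alleles in the window).
#' @export
windowed_pi <- function(g, samples = NULL, windows) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(samples)) samples <- g$samples
  if (length(samples) == 0) stop("empty sample set")
  sub <- g$geno[, samples, drop = FALSE]
  nonmiss <- 2L * rowSums(!is.na(sub))
  j <- rowSums(sub, na.rm = TRUE)
  site_pi <- ifelse(nonmiss >= 2, 2 * j * (nonmiss - j) /
                      (nonmiss * pmax(nonmiss - 1, 1)), 0)
  usable <- nonmiss >= 2 & j > 0 & j < nonmiss
  res <- windows
  res$pi <- NA_real_
  res$n_sites <- 0L
  for (i in seq_len(nrow(windows))) {
    idx <- .sites_in_window(g, windows$chrom[i], windows$start[i],
                            windows$end[i])
    res$pi[i] <- sum(site_pi[idx]) / (windows$end[i] - windows$start[i])
    res$n_sites[i] <- sum(usable[idx])
  }
  res
}

# Weir & Cockerham (1984) per-site variance components for two populations.
# Returns a matrix with columns a, b, c (NA rows where undefined).
.wc_components <- function(g1, g2) {
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  ok <- n1 >= 2 & n2 >= 2
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowMeans(g1 == 1L, na.rm = TRUE)
  h2 <- rowMeans(g2 == 1L, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  out <- cbind(a = a, b = b, c = c_)
  out[!ok, ] <- NA_real_
  # monomorphic across both populations: components are all zero; leave as is
  out
}

#' Windowed Weir-Cockerham FST
#'
#' Per-site Weir & Cockerham (1984) variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals) are computed from the two populations' sample sizes, allele
#' frequencies and observed heterozygote frequencies; the window estimate is
#' the ratio of sums, sum(a) / sum(a + b + c), over sites in the window
#' (`NaN` when the denominator is zero). Values are reported unclamped:
#' negative estimates are meaningful for the empirical Z thresholds used
#' downstream.
#'
#' @param g a `genotype_matrix`.
#' @param popmap data.frame with columns `sample`, `population`; exactly two
#'   populations must be present.
#' @param windows data.frame from [make_windows()].
#' @return data.frame `chrom`, `start`, `end`, `fst`, `n_sites`.
#' @export
windowed_wc_fst <- function(g, popmap, windows) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- unique(popmap$population)
  if (length(pops) != 2) stop("exactly two populations required")
  s1 <- intersect(popmap$sample[popmap$population == pops[1]], g$samples)
  s2 <- intersect(popmap$sample[popmap$population == pops[2]], g$samples)
  if (!length(s1) || !length(s2))
    stop("population absent from genotype matrix")
  comp <- .wc_components(g$geno[, s1, drop = FALSE],
                         g$geno[, s2, drop = FALSE])
  res <- windows
  res$fst <- NA_real_
  res$n_sites <- 0L
  for (i in seq_len(nrow(windows))) {
    idx <- .sites_in_window(g, windows$chrom[i], windows$start[i],
                            windows$end[i])
    cc <- comp[idx, , drop = FALSE]
    cc <- cc[stats::complete.cases(cc), , drop = FALSE]
    num <- sum(cc[, "a"])
    den <- sum(cc)
    res$fst[i] <- if (nrow(cc) == 0 || den == 0) NaN else num / den
    res$n_sites[i] <- nrow(cc)
  }
  res
}

#' Per-sample heterozygosity
#'
#' Proportion of a sample's non-missing genotyped sites that are
#' heterozygous.
#'
#' @param g a `genotype_matrix`.
#' @param sample sample id.
#' @return fraction in `[0, 1]`.
#' @export
sample_heterozygosity <- function(g, sample) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!sample %in% g$samples) stop("sample absent: ", sample)
  x <- g$geno[, sample]
  x <- x[!is.na(x)]
  if (!length(x)) stop("no non-missing genotypes for ", sample)
  mean(x == 1L)
}

#' Method-of-moments inbreeding coefficient
#'
#' F = (O_hom - E_hom) / (M - E_hom), where O_hom is the sample's observed
#' homozygous site count, M its genotyped site count, and
#' E_hom = sum over sites of `1 - 2 p q n / (n - 1)` with p the cohort
#' alternate-allele frequency and n the number of non-missing alleles in the
#' cohort at that site (the estimator reported as F by standard genotype QC
#' tools). Returns `NaN` when M = E_hom (e.g. every usable site fixed).
#'
#' @param g a `genotype_matrix`; cohort frequencies are taken over all its
#'   samples.
#' @param sample sample id.
#' @return real; typically in `[-1, 1]`.
#' @export
inbreeding_coefficient <- function(g, sample) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!sample %in% g$samples) stop("sample absent: ", sample)
  n_alleles <- 2L * rowSums(!is.na(g$geno))
  p <- rowSums(g$geno, na.rm = TRUE) / n_alleles
  ok <- n_alleles >= 2 & !is.na(g$geno[, sample])
  n <- n_alleles[ok]
  pq <- p[ok] * (1 - p[ok])
  e_hom <- sum(1 - 2 * pq * n / (n - 1))
  o_hom <- sum(g$geno[ok, sample] != 1L)
  m <- sum(ok)
  if (abs(m - e_hom) < .Machine$double.eps * m) return(NaN)
  (o_hom - e_hom) / (m - e_hom)
}

#' Convert a per-generation mutation rate to per-year
#'
#' Divides the per-generation rate by the generation time in years; used to
#' place coalescent-scaled demographic inferences on a calendar time scale.
#'
#' @param rate_per_generation substitutions per site per generation (> 0).
#' @param generation_time_years mean generation time in years (> 0).
#' @return substitutions per site per year.
#' @examples
#' convert_mutation_rate(8.42e-9, 4) # 2.105e-09
#' @export
convert_mutation_rate <- function(rate_per_generation, generation_time_years) {
  if (rate_per_generation <= 0 || generation_time_years <= 0)
    stop("both inputs must be positive")
  rate_per_generation / generation_time_years
}
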