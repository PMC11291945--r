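#' Detect runs of homozygosity for one sample
#'
#' PLINK-style sliding-window scan. A window of `window_snps` consecutive
#' sites passes if it contains at most `max_het` heterozygous and at most
#' `max_missing` missing calls. A site is ROH-eligible when at least
#' `hit_fraction` of the windows covering it pass. Maximal runs of eligible
#' sites are then reported if they hold at least `min_snps` sites, span at
#' least `min_kb` kb, have at least one site per `max_inverse_density` kb and
#' contain no inter-site gap above `max_gap_kb` kb (runs are split at larger
#' gaps). Defaults mirror the documented defaults of the standard tool.
#'
#' @param g a `genotype_matrix` (sites sorted within scaffold, as enforced by
#'   the constructor).
#' @param sample sample id.
#' @param window_snps,max_het,max_missing scanning-window parameters.
#' @param hit_fraction minimum fraction of passing covering windows.
#' @param min_snps,min_kb,max_inverse_density,max_gap_kb run-level filters.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open, bp),
#'   `n_snps`, `length_kb`; zero rows if no run qualifies.
#' @export
detect_roh <- function(g, sample, window_snps = 50L, max_het = 1L,
                       max_missing = 5L, hit_fraction = 0.05,
                       min_snps = 100L, min_kb = 1000, max_inverse_density = 50,
                       max_gap_kb = 1000) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!sample %in% g$samples) stop("sample absent: ", sample)
  out <- list()
  for (sc in unique(g$chrom)) {
    idx <- which(g$chrom == sc)
    x <- g$geno[idx, sample]
    pos <- g$pos[idx]
    m <- length(x)
    if (m == 0) next
    het <- as.integer(!is.na(x) & x == 1L)
    mis <- as.integer(is.na(x))
    w <- min(window_snps, m)
    n_win <- m - w + 1L
    ch <- cumsum(c(0L, het)); cm <- cumsum(c(0L, mis))
    win_pass <- (ch[(w + 1):(m + 1)] - ch[1:n_win]) <= max_het &
      (cm[(w + 1):(m + 1)] - cm[1:n_win]) <= max_missing
    # windows covering site i: starts max(1, i-w+1) .. min(i, n_win)
    cp <- cumsum(c(0L, as.integer(win_pass)))
    lo <- pmax(1L, seq_len(m) - w + 1L)
    hi <- pmin(seq_len(m), n_win)
    n_cov <- pmax(hi - lo + 1L, 0L)
    n_pass <- ifelse(n_cov > 0, cp[hi + 1L] - cp[lo], 0L)
    eligible <- n_cov > 0 & n_pass / pmax(n_cov, 1L) >= hit_fraction
    # maximal eligible runs, split at gaps > max_gap_kb
    r <- rle(eligible)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts_i[k]; i1 <- ends_i[k]
      run_pos <- pos[i0:i1]
      gaps <- diff(run_pos)
      brk <- which(gaps > max_gap_kb * 1000)
      seg_start <- c(1L, brk + 1L)
      seg_end <- c(brk, length(run_pos))
      for (s in seq_along(seg_start)) {
        p0 <- run_pos[seg_start[s]]; p1 <- run_pos[seg_end[s]]
        n_snp <- seg_end[s] - seg_start[s] + 1L
        span <- p1 - p0 + 1L
        if (n_snp >= min_snps && span >= min_kb * 1000 &&
            span / n_snp <= max_inverse_density * 1000) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = sc, start = p0 - 1L, end = p1, n_snps = n_snp,
            length_kb = span / 1000)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      length_kb = numeric()))
  do.call(rbind, out)
}

#' Linkage-disequilibrium decay
#'
#' For every intra-scaffold SNP pair within `max_dist_kb`, r-squared is the
#' squared Pearson correlation of the two dosage vectors over
#' pairwise-complete samples (composite LD; phase-free). Pairs are binned by
#' inter-SNP distance and the mean r-squared per bin is reported together
#' with the half-decay distance: the midpoint of the first bin whose mean
#' r-squared drops to half the maximum bin mean or below.
#'
#' @param g a `genotype_matrix`.
#' @param samples sample ids (default all).
#' @param max_dist_kb maximum pair distance in kb (default 501).
#' @param bin_kb bin width in kb.
#' @return list with `bins` (data.frame `dist_lo`, `dist_hi`, `mid_bp`,
#'   `mean_r2`, `n_pairs`) and `half_decay_bp`.
#' @export
ld_decay <- function(g, samples = NULL, max_dist_kb = 501, bin_kb = 10) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(samples)) samples <- g$samples
  max_d <- max_dist_kb * 1000
  n_bins <- ceiling(max_dist_kb / bin_kb)
  sum_r2 <- numeric(n_bins); n_pairs <- integer(n_bins)
  for (sc in unique(g$chrom)) {
    idx <- which(g$chrom == sc)
    if (length(idx) < 2) next
    pos <- g$pos[idx]
    geno <- g$geno[idx, samples, drop = FALSE]
    for (i in seq_len(length(idx) - 1)) {
      js <- which(pos > pos[i] & pos - pos[i] <= max_d)
      for (jj in js) {
        r2 <- pair_r2(geno[i, ], geno[jj, ])
        if (is.na(r2)) next
        b <- min(n_bins, floor((pos[jj] - pos[i]) / (bin_kb * 1000)) + 1L)
        sum_r2[b] <- sum_r2[b] + r2
        n_pairs[b] <- n_pairs[b] + 1L
      }
    }
  }
  lo <- (seq_len(n_bins) - 1L) * bin_kb * 1000
  bins <- data.frame(dist_lo = lo, dist_hi = lo + bin_kb * 1000,
                     mid_bp = lo + bin_kb * 500,
                     mean_r2 = ifelse(n_pairs > 0, sum_r2 / pmax(n_pairs, 1),
                                      NA_real_),
                     n_pairs = n_pairs)
  list(bins = bins, half_decay_bp = half_decay_distance(bins))
}

#' Squared dosage correlation between two sites
#'
#' @param x,y dosage vectors over the same samples; missing entries are
#'   dropped pairwise.
#' @return r-squared, or `NA` when either site is monomorphic over the
#'   complete pairs.
#' @export
pair_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Half-decay distance from binned LD
#'
#' @param bins data.frame with `mean_r2` and `mid_bp` (as from [ld_decay()]).
#' @return midpoint (bp) of the first bin whose mean r-squared is at most
#'   half the maximum bin mean; `NA` if none.
#' @export
half_decay_distance <- function(bins) {
  m <- bins$mean_r2
  if (all(is.na(m))) return(NA_real_)
  half <- max(m, na.rm = TRUE) / 2
  hit <- which(!is.na(m) & m <= half)
  if (!length(hit)) return(NA_real_)
  bins$mid_bp[hit[1]]
}
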