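# Independent brute-force oracles and tiny fixture builders.
# These deliberately re-derive the classical formulas by enumeration so the
# package implementations are checked against something they do not share
# code with.

# genotype matrix from an integer matrix (sites x samples)
toy_gm <- function(m, chrom = NULL, pos = NULL) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("i", seq_len(ncol(m)))
  if (is.null(chrom)) chrom <- rep("c1", nrow(m))
  if (is.null(pos)) pos <- seq_len(nrow(m))
  genotype_matrix(m, chrom, pos)
}

# site pi by enumerating all allele pairs
brute_site_pi <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  alleles <- unlist(lapply(d, function(x) c(rep(1L, x), rep(0L, 2 - x))))
  n <- length(alleles)
  if (n < 2) return(0)
  diff_pairs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    diff_pairs <- diff_pairs + (alleles[i] != alleles[j])
  diff_pairs / choose(n, 2)
}

brute_window_pi <- function(m, window_len) {
  sum(apply(m, 1, brute_site_pi)) / window_len
}

# Weir & Cockerham (1984) theta-hat for one site, two populations,
# written scalar-by-scalar from the published component definitions
brute_wc_site <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2); r <- 2
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

brute_wc_window <- function(m, idx1, idx2) {
  comp <- t(apply(m, 1, function(row) brute_wc_site(row[idx1], row[idx2])))
  sum(comp[, "a"]) / sum(comp)
}

# upper-tail hypergeometric by explicit enumeration
brute_hyper_tail <- function(k, n_bg, k_term, n_set) {
  i <- k:min(k_term, n_set)
  sum(choose(k_term, i) * choose(n_bg - k_term, n_set - i)) /
    choose(n_bg, n_set)
}

# alignment segment from a character vector of equal-length strings
toy_segment <- function(seqs, chrom = "c1", start = 0, focal = names(seqs)[1]) {
  rows <- do.call(rbind, strsplit(seqs, ""))
  rownames(rows) <- names(seqs)
  foc_len <- sum(rows[focal, ] != "-")
  alignment_segment(rows, chrom, start, start + foc_len, focal)
}

# ortholog group from a named character vector (first entry = focal)
toy_group <- function(seqs, gene = "g1") {
  rows <- do.call(rbind, strsplit(seqs, ""))
  rownames(rows) <- c("focal", names(seqs)[-1])
  list(gene = gene, alignment = rows, n_partners = nrow(rows) - 1L)
}
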