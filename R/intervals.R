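# Base-R interval arithmetic on data.frames of 0-based half-open intervals
# (columns chrom, start, end). Kept dependency-free and allocation-light:
# the Monte Carlo overlap null re-intersects region sets tens of thousands
# of times.

# merge overlapping/book-ended intervals; gaps <= max_gap are bridged
merge_intervals <- function(df, max_gap = 0L) {
  if (nrow(df) == 0) return(df[, c("chrom", "start", "end")])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out_chrom <- character(0); out_start <- numeric(0); out_end <- numeric(0)
  cur_c <- df$chrom[1]; cur_s <- df$start[1]; cur_e <- df$end[1]
  for (i in seq_len(nrow(df))[-1]) {
    if (df$chrom[i] == cur_c && df$start[i] <= cur_e + max_gap) {
      cur_e <- max(cur_e, df$end[i])
    } else {
      out_chrom <- c(out_chrom, cur_c)
      out_start <- c(out_start, cur_s); out_end <- c(out_end, cur_e)
      cur_c <- df$chrom[i]; cur_s <- df$start[i]; cur_e <- df$end[i]
    }
  }
  data.frame(chrom = c(out_chrom, cur_c),
             start = as.integer(c(out_start, cur_s)),
             end = as.integer(c(out_end, cur_e)))
}

# intersection of two merged (disjoint, sorted) interval sets
intersect_two <- function(a, b) {
  res_c <- character(0); res_s <- integer(0); res_e <- integer(0)
  for (sc in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == sc, , drop = FALSE]
    bi <- b[b$chrom == sc, , drop = FALSE]
    i <- 1L; j <- 1L
    while (i <= nrow(ai) && j <= nrow(bi)) {
      s <- max(ai$start[i], bi$start[j])
      e <- min(ai$end[i], bi$end[j])
      if (s < e) {
        res_c <- c(res_c, sc); res_s <- c(res_s, s); res_e <- c(res_e, e)
      }
      if (ai$end[i] < bi$end[j]) i <- i + 1L else j <- j + 1L
    }
  }
  data.frame(chrom = res_c, start = res_s, end = res_e)
}

# total bp covered
interval_span <- function(df) if (nrow(df) == 0) 0 else sum(df$end - df$start)
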