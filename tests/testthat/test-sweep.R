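mk_stat <- function(value, name, n_sites = 10) {
  n <- length(value)
  df <- data.frame(chrom = "s1", start = (seq_len(n) - 1) * 10000,
                   end = (seq_len(n) - 1) * 10000 + 50000)
  df[[name]] <- value
  df$n_sites <- n_sites
  df
}

test_that("ln diversity ratio is oriented so sweeps in the target are positive", {
  pi_t <- mk_stat(c(0.001, 0.004, 0), "pi")
  pi_r <- mk_stat(c(0.004, 0.004, 0.004), "pi")
  res <- ln_diversity_ratio(pi_t, pi_r)
  expect_equal(res$ln_ratio, c(log(4), 0), tolerance = 1e-12)
  expect_equal(nrow(attr(res, "dropped")), 1L)       # pi_target = 0 excluded
  flipped <- ln_diversity_ratio(pi_t, pi_r, orientation = "target_over_ref")
  expect_equal(flipped$ln_ratio, -res$ln_ratio)
  expect_error(ln_diversity_ratio(pi_t[1:2, ], pi_r), "tilings")
})

test_that("empirical Z threshold is mean + 1.6449 sd at alpha 0.05", {
  set.seed(2)
  x <- rnorm(5000)
  th <- empirical_z_thresholds(x, 0.05)
  expect_equal(th, mean(x) + qnorm(0.95) * sd(x), tolerance = 1e-12)
  expect_equal(qnorm(0.95), 1.6449, tolerance = 1e-4)
  expect_equal(empirical_z_thresholds(x, 0.5), mean(x), tolerance = 1e-12)
  expect_error(empirical_z_thresholds(rep(1, 100)), "variance")
  expect_error(empirical_z_thresholds(rnorm(10)), ">= 30")
})

test_that("window selection applies the joint FST / ln-ratio rule", {
  fst <- mk_stat(c(0.2, 0.2, 0.1), "fst")
  lnr <- mk_stat(c(0.4, 0.3, 0.4), "ln_ratio")
  sel <- call_selected_windows(fst, lnr, 0.186, 0.332)
  expect_equal(nrow(sel), 1L)      # only the window passing both thresholds
  expect_equal(sel$start, 0)
  # monotonicity: raising either threshold never adds windows
  base <- call_selected_windows(fst, lnr, 0.05, 0.1)
  for (d in c(0.05, 0.15)) {
    up_f <- call_selected_windows(fst, lnr, 0.05 + d, 0.1)
    up_l <- call_selected_windows(fst, lnr, 0.05, 0.1 + d)
    expect_true(all(paste(up_f$start) %in% paste(base$start)))
    expect_true(all(paste(up_l$start) %in% paste(base$start)))
  }
  empty <- call_selected_windows(fst[0, ], lnr[0, ], 0.186, 0.332)
  expect_equal(nrow(empty), 0L)
})

test_that("overlapping windows merge into maximal regions per scaffold", {
  win <- data.frame(chrom = c("s1", "s1", "s2"),
                    start = c(0, 10000, 0), end = c(50000, 60000, 50000),
                    fst = c(0.3, 0.4, 0.2), ln_ratio = c(1, 2, 1.5))
  reg <- merge_windows_to_regions(win, label = "cmp")
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$end[reg$chrom == "s1"], 60000)
  expect_equal(reg$n_windows[reg$chrom == "s1"], 2L)
  expect_equal(reg$max_fst[reg$chrom == "s1"], 0.4)
  disj <- data.frame(chrom = "s1", start = c(0, 2, 4) * 1e5,
                     end = c(0, 2, 4) * 1e5 + 5e4)
  expect_equal(nrow(merge_windows_to_regions(disj)), 3L)
})

test_that("region-set intersection follows interval arithmetic", {
  s1 <- data.frame(chrom = "c", start = 0, end = 100)
  s2 <- data.frame(chrom = "c", start = 50, end = 150)
  s3 <- data.frame(chrom = "c", start = 80, end = 200)
  res <- intersect_region_sets(list(s1, s2, s3))
  expect_equal(res, data.frame(chrom = "c", start = 80, end = 100))
  expect_equal(intersect_region_sets(list(s1, s1, s1))[, 2:3], s1[, 2:3])
  far <- data.frame(chrom = "c", start = 500, end = 600)
  expect_equal(nrow(intersect_region_sets(list(s1, far))), 0L)
})

test_that("Monte Carlo overlap p-value matches the analytic toy and is deterministic", {
  sets <- rep(list(data.frame(chrom = "s", start = 0, end = 1)), 3)
  mc <- monte_carlo_overlap_pvalue(sets, c(s = 10), n_iter = 10000, seed = 4)
  se <- sqrt(0.01 * 0.99 / 10000)
  expect_lt(abs(mc$p_value - 0.01), 3 * se)
  expect_equal(mc$p_value,
               monte_carlo_overlap_pvalue(sets, c(s = 10), n_iter = 10000,
                                          seed = 4)$p_value)
  # saturated: full-scaffold regions always reproduce the observed overlap
  sat <- monte_carlo_overlap_pvalue(
    rep(list(data.frame(chrom = "s", start = 0, end = 10)), 3),
    c(s = 10), n_iter = 500, seed = 1)
  expect_identical(sat$p_value, 1)
  expect_error(monte_carlo_overlap_pvalue(
    list(data.frame(chrom = "s", start = 0, end = 50),
         data.frame(chrom = "s", start = 0, end = 1)), c(s = 10)),
    "fits on no scaffold")
})

test_that("regions are annotated with every overlapping gene", {
  genes <- data.frame(chrom = c("s1", "s1", "s2"),
                      start = c(100, 400, 0), end = c(300, 600, 100),
                      strand = "+", gene_id = c("gA", "gB", "gC"))
  reg <- data.frame(chrom = c("s1", "s1", "s3"),
                    start = c(150, 250, 0), end = c(500, 280, 100))
  ann <- annotate_regions_with_genes(reg, genes)
  expect_equal(ann$genes, c("gA,gB", "gA", "none"))
})

test_that("planted sweeps are called and null windows stay near the alpha level", {
  sw <- data.frame(chrom = paste0("scaf_", 1:4),
                   start = c(10, 12, 14, 16) * 1e5,
                   end = c(10, 12, 14, 16) * 1e5 + 5e4,
                   diversity_reduction = 0.2)
  sim <- simulate_population_genotypes(n_samples_per_pop = 20,
                                       n_scaffolds = 4,
                                       scaffold_length = 5e6,
                                       snp_density = 0.001,
                                       target_fst = 0.10,
                                       sweep_windows = sw, seed = 21)
  g <- sim$genotypes
  w <- make_windows(sim$scaffold_lengths)
  wild <- sim$popmap$sample[sim$popmap$population == "wild"]
  dom <- sim$popmap$sample[sim$popmap$population == "domestic"]
  pi_w <- windowed_pi(g, wild, w); pi_d <- windowed_pi(g, dom, w)
  fst <- windowed_wc_fst(g, sim$popmap, w)
  lnr <- ln_diversity_ratio(pi_d, pi_w)
  sel <- call_selected_windows(fst, lnr,
                               empirical_z_thresholds(fst$fst[is.finite(fst$fst)]),
                               empirical_z_thresholds(lnr$ln_ratio))
  recovered <- vapply(seq_len(nrow(sw)), function(i)
    any(sel$chrom == sw$chrom[i] & sel$start < sw$end[i] &
          sel$end > sw$start[i]), TRUE)
  expect_gte(mean(recovered), 0.8)
  # pi ratio sensitivity in the planted windows
  idx <- match(paste(sw$chrom, format(sw$start, scientific = FALSE)),
               paste(pi_d$chrom, pi_d$start))
  expect_true(all(pi_d$pi[idx] / pi_w$pi[idx] < 0.5))

  # null: no sweeps planted; joint selection stays at or below alpha
  sim0 <- simulate_population_genotypes(n_samples_per_pop = 20,
                                        n_scaffolds = 2,
                                        scaffold_length = 5e6,
                                        snp_density = 0.001,
                                        target_fst = 0.10, seed = 22)
  w0 <- make_windows(sim0$scaffold_lengths)
  f0 <- windowed_wc_fst(sim0$genotypes, sim0$popmap, w0)
  p0w <- windowed_pi(sim0$genotypes,
                     sim0$popmap$sample[sim0$popmap$population == "wild"], w0)
  p0d <- windowed_pi(sim0$genotypes,
                     sim0$popmap$sample[sim0$popmap$population == "domestic"],
                     w0)
  l0 <- ln_diversity_ratio(p0d, p0w)
  s0 <- call_selected_windows(
    f0, l0, empirical_z_thresholds(f0$fst[is.finite(f0$fst)]),
    empirical_z_thresholds(l0$ln_ratio))
  expect_lte(nrow(s0) / nrow(l0), 0.05)
})
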