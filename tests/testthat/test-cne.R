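sp16 <- sprintf("sp%02d", 1:16)

# an element of `len` columns identical across all species, with optional
# focal edits
mk_element <- function(len, focal_variant_cols = integer(0),
                       focal_gap_frac = 0, nonfocal_noise_cols = integer(0),
                       start = 0) {
  set.seed(len + length(focal_variant_cols))
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  rows <- matrix(rep(base, each = 16), nrow = 16,
                 dimnames = list(sp16, NULL))
  flip <- function(x) c(A = "C", C = "G", G = "T", T = "A")[[x]]
  for (j in focal_variant_cols) rows["sp01", j] <- flip(base[j])
  # noise: 8 of the 15 non-focal species get scattered other bases, so the
  # column majority stays the original base at fraction 7/15
  for (j in nonfocal_noise_cols)
    rows[sample(sp16[-1], 8), j] <- sample(setdiff(c("A", "C", "G", "T"),
                                                   base[j]), 8,
                                           replace = TRUE)
  if (focal_gap_frac > 0) {
    ngap <- round(focal_gap_frac * len)
    rows["sp01", seq_len(ngap)] <- "-"
  }
  foc_len <- sum(rows["sp01", ] != "-")
  alignment_segment(rows, "scaf_1", start, start + foc_len, "sp01")
}

test_that("conservation score averages column-majority agreement", {
  seg <- mk_element(100)
  expect_equal(conservation_score(seg, sp16), 1.0)
  # 2 species, 10 columns, one mismatch: mean of nine 1.0 and one 0.5
  two <- toy_segment(c(a = "AAAAAAAAAA", b = "AAAAAAAAAC"), focal = "a")
  expect_equal(conservation_score(two, c("a", "b")), 0.95)
  # one of 3 species entirely gapped: 2/3 per column
  three <- toy_segment(c(a = "ACGT", b = "ACGT", c = "----"), focal = "a")
  expect_equal(conservation_score(three, c("a", "b", "c")), 2 / 3,
               tolerance = 1e-12)
  # a species absent from the segment counts as mismatching
  expect_equal(conservation_score(two, c("a", "b", "zz")),
               (9 * 2 / 3 + 1 / 3) / 10, tolerance = 1e-12)
})

test_that("exonic columns are excised and segments split", {
  seg <- mk_element(300, start = 1000)
  exons <- data.frame(chrom = "scaf_1", start = 1100, end = 1200,
                      strand = "+", gene_id = "e1")
  out <- extract_noncoding_segments(list(seg), exons, min_len = 50)
  expect_equal(length(out), 2L)
  expect_equal(c(out[[1]]$start, out[[1]]$end), c(1000, 1100))
  expect_equal(c(out[[2]]$start, out[[2]]$end), c(1200, 1300))
  # fully exonic segment removed; intergenic passed through
  inside <- extract_noncoding_segments(
    list(mk_element(80, start = 1110)), exons, min_len = 50)
  expect_equal(length(inside), 0L)
  free <- extract_noncoding_segments(
    list(mk_element(80, start = 5000)), exons, min_len = 50)
  expect_equal(length(free), 1L)
  expect_equal(ncol(free[[1]]$rows), 80L)
})

test_that("candidate CNEs require >80% non-focal conservation and min length", {
  segs <- list(mk_element(140),                       # perfect
               mk_element(100, nonfocal_noise_cols = 1:45), # cons ~ 0.775
               mk_element(40))                        # too short
  cand <- find_conserved_elements(segs, sp16, "sp01")
  expect_equal(cand$segment, 1L)
  cons_noisy <- conservation_score(segs[[2]], sp16[-1])
  expect_lt(cons_noisy, 0.8)
  # boundary: conservation just below vs just above the 0.8 cutoff
  lo <- mk_element(100, nonfocal_noise_cols = 1:40)   # ~0.787
  hi <- mk_element(100, nonfocal_noise_cols = 1:35)   # ~0.813
  expect_equal(conservation_score(lo, sp16[-1]), 0.79, tolerance = 0.015)
  expect_equal(nrow(find_conserved_elements(list(lo), sp16, "sp01")), 0L)
  expect_equal(nrow(find_conserved_elements(list(hi), sp16, "sp01")), 1L)
})

test_that("lost elements are focal-absent or heavily focal-gapped", {
  full_gap <- mk_element(100, focal_gap_frac = 1)
  part_gap <- mk_element(100, focal_gap_frac = 0.85)
  ok_gap <- mk_element(100, focal_gap_frac = 0.10)
  segs <- list(full_gap, part_gap, ok_gap)
  cand <- find_conserved_elements(segs, sp16, "sp01")
  lost <- classify_lost(cand, segs)
  expect_setequal(lost$segment, c(1L, 2L))
  # focal present at high identity is not lost
  expect_false(3L %in% lost$segment)
})

test_that("divergent calls need >=10 contiguous focal variants and 16-way conservation", {
  div12 <- mk_element(140, focal_variant_cols = 21:32)   # 12 contiguous
  div9 <- mk_element(140, focal_variant_cols = 21:29)    # 9: below cutoff
  broken <- mk_element(140, focal_variant_cols = c(21:25, 27:31)) # run of 5
  segs <- list(div12, div9, broken)
  cand <- find_conserved_elements(segs, sp16, "sp01")
  divg <- classify_divergent(cand, segs, sp16, "sp01")
  expect_equal(divg$segment, 1L)
  expect_gte(divg$max_contiguous_focal_variants, 10L)
  expect_gt(divg$all_species_conservation, 0.8)
  # 12 contiguous variants but low 16-way conservation fails the joint rule
  weak <- mk_element(60, focal_variant_cols = 21:32,
                     nonfocal_noise_cols = c(1:18, 41:59))
  expect_lt(conservation_score(weak, sp16), 0.8)
  cand_w <- data.frame(chrom = "scaf_1", start = 0, end = 60, segment = 1L,
                       nonfocal_conservation = NA, class = "conserved")
  expect_equal(nrow(classify_divergent(cand_w, list(weak), sp16, "sp01")), 0L)
  # raising min_contiguous never adds calls
  d10 <- classify_divergent(cand, segs, sp16, "sp01", min_contiguous = 10)
  d12 <- classify_divergent(cand, segs, sp16, "sp01", min_contiguous = 13)
  expect_true(all(d12$segment %in% d10$segment))
})

test_that("planted lost and divergent CNEs are recovered exactly when noiseless", {
  dir <- withr::local_tempdir()
  aln <- simulate_species_alignment(conserved_rate_scale = 0, seed = 11,
                                    out_dir = dir)
  segs <- read_maf(file.path(dir, "alignment.maf"))
  exons <- read_gff3(file.path(dir, "genes.gff3"), feature = "exon")
  nc <- extract_noncoding_segments(segs, exons)
  cand <- find_conserved_elements(nc, aln$species, aln$focal)
  lost <- classify_lost(cand, nc)
  divg <- classify_divergent(cand, nc, aln$species, aln$focal)
  truth <- aln$truth
  expect_setequal(paste(lost$chrom, lost$start),
                  paste(truth$truth_lost_cnes$chrom,
                        truth$truth_lost_cnes$start))
  expect_setequal(paste(divg$chrom, divg$start, divg$end),
                  paste(truth$truth_divergent_cnes$chrom,
                        truth$truth_divergent_cnes$start,
                        truth$truth_divergent_cnes$end))
  # coordinate round-trip: candidates map back to generating blocks exactly
  gen_keys <- vapply(aln$segments, function(s)
    paste(s$chrom, s$start, s$end), "")
  expect_true(all(paste(cand$chrom, cand$start, cand$end) %in% gen_keys))
})

test_that("nearest gene assignment is signed, strand-aware and tie-friendly", {
  genes <- data.frame(chrom = "s1", start = c(100000, 200000),
                      end = c(105000, 205000), strand = c("+", "-"),
                      gene_id = c("FWD", "REV"))
  # midpoint 42000, 58 kb upstream of the plus-strand gene start
  cne <- data.frame(chrom = "s1", start = 41900, end = 42100)
  res <- nearest_gene(cne, genes)
  expect_equal(res$gene_id, "FWD")
  expect_equal(res$distance, -58000)
  # inside the span: distance 0
  inside <- nearest_gene(data.frame(chrom = "s1", start = 102000,
                                    end = 102100), genes)
  expect_equal(inside$distance, 0)
  # upstream of a minus-strand gene means beyond its end coordinate
  up_rev <- nearest_gene(data.frame(chrom = "s1", start = 214950,
                                    end = 215050), genes)
  expect_equal(up_rev$gene_id, "REV")
  expect_equal(up_rev$distance, -10000)
  # equidistant genes: both reported
  tie <- nearest_gene(data.frame(chrom = "s1", start = 152450,
                                 end = 152550), genes)
  expect_setequal(tie$gene_id, c("FWD", "REV"))
  # gene-free scaffold
  none <- nearest_gene(data.frame(chrom = "s9", start = 0, end = 10), genes)
  expect_equal(none$gene_id, "none")
})

test_that("hypergeometric enrichment equals exact tail enumeration with monotone BH", {
  background <- paste0("g", 1:20)
  term_map <- rbind(data.frame(gene = paste0("g", 1:5), term = "T1"),
                    data.frame(gene = background, term = "T_all"),
                    data.frame(gene = paste0("g", c(1, 6, 7)), term = "T2"))
  gene_set <- paste0("g", c(1:4, 6))   # overlap with T1 = 4 of K=5, n=5
  res <- hypergeometric_enrichment(gene_set, background, term_map)
  expect_equal(res$raw_p[res$term == "T1"], 76 / 15504, tolerance = 1e-12)
  expect_equal(res$raw_p[res$term == "T1"],
               brute_hyper_tail(4, 20, 5, 5), tolerance = 1e-12)
  expect_equal(res$raw_p[res$term == "T_all"], 1)
  expect_true(all(res$adj_p >= res$raw_p - 1e-15))
  # BH keeps the p ordering monotone
  ord <- order(res$raw_p)
  expect_true(all(diff(res$adj_p[ord]) >= -1e-15))
  # gene_set = background: every overlap is K, p = 1
  all_res <- hypergeometric_enrichment(background, background, term_map)
  expect_true(all(all_res$raw_p == 1))
  expect_error(hypergeometric_enrichment("g1", character(0), term_map),
               "empty background")
})
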