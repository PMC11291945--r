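test_that("reciprocal best hits recover identity mappings and drop ties", {
  a <- c(x1 = "MKTLLVAAGLLSDERKW", x2 = "MNPQRSTVWYACDEFGH", x3 = "MHHHHKKKKLLLLPPPP")
  names_b <- c("y1", "y2", "y3")
  b <- setNames(a, names_b)
  rbh <- reciprocal_best_hits(a, b)
  expect_equal(rbh$id_a, names(a))
  expect_equal(rbh$id_b, names_b)
  # a gene with two equal best hits is unpaired
  b_tie <- c(b, y1bis = unname(a["x1"]))
  rbh_tie <- reciprocal_best_hits(a, b_tie)
  expect_false("x1" %in% rbh_tie$id_a)
  expect_true(all(c("x2", "x3") %in% rbh_tie$id_a))
  expect_error(reciprocal_best_hits(a, character(0)), "empty")
})

test_that("RBH pairing equals exhaustive score-matrix inspection and is symmetric", {
  set.seed(13)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mk <- function(n, L) setNames(
    vapply(seq_len(n), function(i) paste(sample(aa, L, replace = TRUE),
                                         collapse = ""), ""),
    paste0("p", seq_len(n)))
  a <- mk(3, 60); b <- setNames(mk(3, 60), c("q1", "q2", "q3"))
  # independent oracle: full score matrix, best hits read off by inspection
  score <- matrix(0, 3, 3, dimnames = list(names(a), names(b)))
  for (i in 1:3) for (j in 1:3)
    score[i, j] <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a[[i]]), Biostrings::AAString(b[[j]]),
      type = "local", substitutionMatrix = "BLOSUM62", gapOpening = 11,
      gapExtension = 1, scoreOnly = TRUE)
  expected <- list()
  for (i in 1:3) {
    j <- which.max(score[i, ])
    if (sum(score[i, ] == max(score[i, ])) == 1 &&
        sum(score[, j] == max(score[, j])) == 1 &&
        which.max(score[, j]) == i)
      expected[[length(expected) + 1]] <- c(names(a)[i], names(b)[j])
  }
  rbh <- reciprocal_best_hits(a, b)
  expect_equal(nrow(rbh), length(expected))
  for (k in seq_along(expected)) {
    expect_equal(rbh$id_a[k], expected[[k]][1])
    expect_equal(rbh$id_b[k], expected[[k]][2])
  }
  # symmetry: swapping proteomes transposes the pairing
  rbh_rev <- reciprocal_best_hits(b, a)
  expect_setequal(paste(rbh$id_a, rbh$id_b),
                  paste(rbh_rev$id_b, rbh_rev$id_a))
})

test_that("ortholog groups require partners in min_species proteomes", {
  pr <- simulate_ortholog_proteomes(n_species = 5, n_genes = 4,
                                    planted_sites = 0, seed = 3)
  others <- pr$proteomes[-1]
  groups <- build_ortholog_groups(pr$proteomes$sp01, others)
  expect_equal(sort(names(groups)), sort(names(pr$proteomes$sp01)))
  expect_true(all(vapply(groups, `[[`, 0L, "n_partners") == 4L))
  # delete one species' ortholog of g001
  others$sp03 <- others$sp03[names(others$sp03) != "sp03_g001"]
  g_strict <- build_ortholog_groups(pr$proteomes$sp01, others,
                                    min_species = 4)
  expect_false("g001" %in% names(g_strict))
  g_loose <- build_ortholog_groups(pr$proteomes$sp01, others,
                                   min_species = 3)
  expect_true("g001" %in% names(g_loose))
  expect_equal(g_loose$g001$n_partners, 3L)
})

test_that("substitution scan applies the consensus, difference and flank rules", {
  # 41-residue protein, focal-specific D->E at column 21, perfect flanks
  base <- strsplit("MKTLLVAAGLLSDERKWQPH D HGFEDCBAAKLMNPQRSTVW", " ")[[1]]
  mkseq <- function(mid) paste0(base[1], mid, base[3])
  grp <- toy_group(c(focal = mkseq("E"), s2 = mkseq("D"), s3 = mkseq("D"),
                     s4 = mkseq("D")))
  res <- scan_specific_substitutions(grp)
  expect_equal(res$column, 21L)
  expect_equal(res$focal_residue, "E")
  expect_equal(res$consensus_residue, "D")
  expect_gt(res$flank_similarity, 0.6)
  # one dissenting non-focal species blocks the call
  grp_dis <- toy_group(c(focal = mkseq("E"), s2 = mkseq("D"),
                         s3 = mkseq("A"), s4 = mkseq("D")))
  expect_equal(nrow(scan_specific_substitutions(grp_dis)), 0L)
  # a gap in a non-focal row blocks the call
  grp_gap <- toy_group(c(focal = mkseq("E"), s2 = mkseq("D"),
                         s3 = mkseq("-"), s4 = mkseq("D")))
  expect_equal(nrow(scan_specific_substitutions(grp_gap)), 0L)
  # columns within 10 residues of a terminus are never called
  short <- toy_group(c(focal = "AAAAAAAAAEAAAAAAAAA", s2 = "AAAAAAAAADAAAAAAAAA",
                       s3 = "AAAAAAAAADAAAAAAAAA"))
  expect_equal(nrow(scan_specific_substitutions(short)), 0L)
})

test_that("low flank similarity rejects an otherwise qualifying site", {
  # flanks scrambled across rows: majority fraction ~ 1/3 per flank column
  set.seed(21)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  scramble <- function() paste(sample(aa, 20, replace = TRUE), collapse = "")
  grp <- toy_group(c(focal = paste0(scramble(), "E", scramble()),
                     s2 = paste0(scramble(), "D", scramble()),
                     s3 = paste0(scramble(), "D", scramble())))
  res <- scan_specific_substitutions(grp)
  expect_equal(nrow(res), 0L)
  # the same site passes once the flanks are conserved
  cons_flank <- paste(rep("K", 20), collapse = "")
  grp_ok <- toy_group(c(focal = paste0(cons_flank, "E", cons_flank),
                        s2 = paste0(cons_flank, "D", cons_flank),
                        s3 = paste0(cons_flank, "D", cons_flank)))
  expect_equal(scan_specific_substitutions(grp_ok)$column, 21L)
})

test_that("planted substitutions are recovered exactly on noiseless proteomes", {
  pr <- simulate_ortholog_proteomes(n_species = 16, n_genes = 8,
                                    planted_sites = 4, seed = 9)
  groups <- build_ortholog_groups(pr$proteomes$sp01, pr$proteomes[-1])
  sites <- scan_all_groups(groups)
  expect_setequal(paste(sites$gene, sites$column),
                  paste(pr$truth$gene, pr$truth$column))
  gw <- genes_with_substitutions(sites)
  expect_equal(gw$count, length(unique(pr$truth$gene)))
  expect_setequal(gw$genes, unique(pr$truth$gene))
  expect_equal(genes_with_substitutions(sites[0, ])$count, 0L)
})

test_that("a zero-site simulation yields a clean scan and determinism holds", {
  pr0 <- simulate_ortholog_proteomes(n_species = 6, n_genes = 5,
                                     planted_sites = 0, seed = 17)
  groups <- build_ortholog_groups(pr0$proteomes$sp01, pr0$proteomes[-1])
  expect_equal(nrow(scan_all_groups(groups)), 0L)
  pr_a <- simulate_ortholog_proteomes(n_species = 4, n_genes = 3,
                                      planted_sites = 2, seed = 8)
  pr_b <- simulate_ortholog_proteomes(n_species = 4, n_genes = 3,
                                      planted_sites = 2, seed = 8)
  expect_identical(pr_a$proteomes, pr_b$proteomes)
  expect_identical(pr_a$truth, pr_b$truth)
})
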