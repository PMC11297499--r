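test_that("generation is byte-exact under a fixed seed", {
  cfg <- generator_config(n_peptides = 5, tcrs_per_peptide = 10, seed = 101)
  g1 <- generate_repertoire(cfg)
  g2 <- generate_repertoire(cfg)
  expect_identical(as.data.frame(g1$positives), as.data.frame(g2$positives))
  expect_identical(as.data.frame(g1$pool), as.data.frame(g2$pool))
  expect_identical(g1$truth$motifs, g2$truth$motifs)
  g3 <- generate_repertoire(generator_config(n_peptides = 5,
                                             tcrs_per_peptide = 10,
                                             seed = 102))
  expect_false(identical(as.data.frame(g1$positives),
                         as.data.frame(g3$positives)))
})

test_that("planted motifs sit at the stated CDR3-beta offset", {
  cfg <- generator_config(n_peptides = 4, tcrs_per_peptide = 15,
                          motif_strength = 1, cross_reactivity_rate = 0,
                          seed = 103)
  g <- generate_repertoire(cfg)
  motif_of <- stats::setNames(g$truth$motifs$motif, g$truth$motifs$peptide)
  expect_true(all(g$truth$records$has_motif))
  carried <- substr(g$positives$B3, 4, 6)
  expect_equal(carried, unname(motif_of[g$positives$peptide]))
  # motif_strength 0 plants nothing
  g0 <- generate_repertoire(generator_config(n_peptides = 4,
                                             tcrs_per_peptide = 15,
                                             motif_strength = 0,
                                             cross_reactivity_rate = 0,
                                             seed = 104))
  expect_false(any(g0$truth$records$has_motif))
})

test_that("power-law counts concentrate records on top peptides", {
  g <- generate_repertoire(
    generator_config(n_peptides = 20, tcrs_per_peptide = 30,
                     count_distribution = "power", power_exponent = 2,
                     cross_reactivity_rate = 0, seed = 105))
  counts <- sort(table(g$positives$peptide), decreasing = TRUE)
  expect_gt(sum(counts[1:5]) / sum(counts), 0.5)
  # uniform counts are exactly equal
  gu <- generate_repertoire(
    generator_config(n_peptides = 6, tcrs_per_peptide = 25,
                     cross_reactivity_rate = 0, seed = 106))
  expect_true(all(table(gu$positives$peptide) == 25))
})

test_that("cross-reactive TCRs appear under two peptides with both motifs", {
  cfg <- generator_config(n_peptides = 6, tcrs_per_peptide = 20,
                          motif_strength = 1, cross_reactivity_rate = 0.2,
                          seed = 107)
  g <- generate_repertoire(cfg)
  key <- tcrpred:::tcr_key(g$positives)
  shared <- names(which(table(key) >= 2))
  expect_gt(length(shared), 0)
  motif_of <- stats::setNames(g$truth$motifs$motif, g$truth$motifs$peptide)
  for (k in utils::head(shared, 5)) {
    rows <- g$positives[key == k, ]
    expect_gt(length(unique(rows$peptide)), 1)
    # each peptide's motif occurs in the shared CDR3-beta
    for (p in unique(rows$peptide)) {
      expect_true(grepl(motif_of[[p]], rows$B3[1], fixed = TRUE))
    }
  }
})

test_that("similarity-linked motifs follow peptide prefixes", {
  g <- generate_repertoire(
    generator_config(n_peptides = 9, tcrs_per_peptide = 5,
                     similarity_link = TRUE, cross_reactivity_rate = 0,
                     seed = 108))
  m <- g$truth$motifs
  # peptides sharing their 3-residue prefix share motifs
  pref <- substr(m$peptide, 1, 3)
  for (p in unique(pref)) {
    expect_length(unique(m$motif[pref == p]), 1L)
  }
  # and the mutation families create near-duplicate peptides
  d <- utils::adist(m$peptide)
  diag(d) <- NA
  expect_true(min(d, na.rm = TRUE) <= 2)
})

test_that("control pool shift moves residue composition, zero preserves it", {
  base <- generator_config(n_peptides = 4, tcrs_per_peptide = 10,
                           control_pool_size = 400,
                           control_composition_shift = 0, seed = 109)
  g0 <- generate_repertoire(base)
  freq_of <- function(pool) {
    ch <- unlist(strsplit(paste0(pool$A3, pool$B3), ""))
    tab <- table(factor(ch, levels = aa_alphabet()))
    as.numeric(tab) / sum(tab)
  }
  f0 <- freq_of(g0$pool)
  expect_lt(max(abs(f0 - 0.05)), 0.02)  # near-uniform at shift 0
  gS <- generate_repertoire(
    generator_config(n_peptides = 4, tcrs_per_peptide = 10,
                     control_pool_size = 400,
                     control_composition_shift = 0.8, seed = 109))
  fS <- freq_of(gS$pool)
  expect_gt(max(abs(fS - 0.05)), 0.03)  # visibly biased at shift 0.8
})

test_that("structure fixtures separate planted and background pairs", {
  rep_ <- small_repertoire()
  rec <- rep_$positives[1, ]
  dm <- generate_structure_fixture(rec, motif_start = 4, motif_length = 3,
                                   complex_id = "fx1", seed = 7)
  expect_s3_class(dm, "distance_map")
  expect_equal(nrow(dm$d), nchar(rec$peptide))
  expect_equal(ncol(dm$d), nchar(rec$B1) + nchar(rec$B2) + nchar(rec$B3))
  planted <- attr(dm, "planted_cols")
  cls <- classify_pairs(dm)
  expect_true(all(cls$labels[, planted] == "close"))     # 9 < 10
  expect_false(any(cls$labels[, -planted] == "close"))   # 12 > 10
  # mixture moments: planted ~ U(4,9), rest ~ U(12,40)
  n_planted <- length(planted) * nrow(dm$d)
  n_far <- length(dm$d) - n_planted
  w <- n_planted / length(dm$d)
  expect_equal(mean(dm$d), w * 6.5 + (1 - w) * 26, tolerance = 0.15)
  # reproducibility
  dm2 <- generate_structure_fixture(rec, motif_start = 4, motif_length = 3,
                                    complex_id = "fx1", seed = 7)
  expect_identical(dm$d, dm2$d)
})

test_that("generator rejects motifs that cannot fit the CDR3-beta slot", {
  expect_error(
    generator_config(n_peptides = 2, tcrs_per_peptide = 5,
                     motif_length = 6, motif_offset = 4,
                     cdr_length = list(A1 = c(5, 7), A2 = c(6, 8),
                                       A3 = c(10, 16), B1 = c(5, 7),
                                       B2 = c(6, 8), B3 = c(12, 16)),
                     seed = 1),
    "must fit")
  expect_error(generator_config(n_peptides = 2, tcrs_per_peptide = 5),
               "seed")
})
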