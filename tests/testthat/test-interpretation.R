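test_that("pair classification applies strict distance thresholds", {
  d <- matrix(c(8, 16, 30, 10, 25, 9.99), 2, 3)
  dm <- distance_map("x", "AC", "DEF", d)
  cls <- classify_pairs(dm)
  expect_equal(cls$labels[1, 1], "close")         # 8 < 10
  expect_equal(cls$labels[1, 2], "far")           # 30 > 25
  expect_equal(cls$labels[2, 1], "intermediate")  # 16
  expect_equal(cls$labels[2, 2], "intermediate")  # boundary 10 excluded
  expect_equal(cls$labels[1, 3], "intermediate")  # boundary 25 excluded
  expect_equal(cls$labels[2, 3], "close")
  # exhaustive and exclusive
  expect_equal(sum(cls$labels %in% c("close", "far", "intermediate")), 6L)
  expect_error(classify_pairs(dm, close_threshold = 30, far_threshold = 25))
})

test_that("per-complex means are masked averages, with undefined flags", {
  d <- matrix(c(5, 30, 15, 5), 2, 2)
  dm <- distance_map("x", "AC", "DE", d)
  cls <- classify_pairs(dm)
  scores <- matrix(c(1, 0, 0.5, 1), 2, 2)
  cm <- complex_mean_scores(scores, cls)
  expect_equal(cm$mean_close, 1)   # scores on the two close pairs
  expect_equal(cm$mean_far, 0)
  expect_true(cm$defined)
  # uniform scores: the two means coincide
  cm_u <- complex_mean_scores(matrix(0.3, 2, 2), cls)
  expect_equal(cm_u$mean_close, cm_u$mean_far)
  # no far pairs: undefined
  dm2 <- distance_map("y", "AC", "DE", matrix(5, 2, 2))
  cm2 <- complex_mean_scores(matrix(1, 2, 2), classify_pairs(dm2))
  expect_true(is.na(cm2$mean_far))
  expect_false(cm2$defined)
  expect_error(complex_mean_scores(matrix(1, 3, 2), cls), "match")
})

test_that("masked means match brute force on fuzzed matrices", {
  withr::with_seed(71, {
    for (i in 1:50) {
      np <- sample(3:9, 1); nb <- sample(5:20, 1)
      d <- matrix(runif(np * nb, 0, 40), np, nb)
      dm <- distance_map("f", strrep("A", np), strrep("C", nb), d)
      cls <- classify_pairs(dm)
      sc <- matrix(runif(np * nb), np, nb)
      cm <- complex_mean_scores(sc, cls)
      if (cm$defined) {
        expect_equal(cm$mean_close, mean(sc[d < 10]), tolerance = 1e-12)
        expect_equal(cm$mean_far, mean(sc[d > 25]), tolerance = 1e-12)
      }
    }
  })
})

test_that("close/far comparison reports group stats and the chosen t-test", {
  withr::with_seed(73, {
    pc <- tibble::tibble(
      complex_id = paste0("c", 1:24),
      mean_close = rnorm(24, 0.09, 0.01),
      mean_far = rnorm(24, 0.078, 0.013),
      n_close = 10L, n_far = 10L, defined = TRUE)
  })
  out <- compare_close_far(pc)
  expect_equal(out$test$variant, "student")
  ref <- t.test(pc$mean_close, pc$mean_far, var.equal = TRUE)
  expect_equal(out$test$p_value, ref$p.value)
  expect_equal(out$test$df, unname(ref$parameter))
  # antisymmetry under swapping the groups
  swapped <- pc
  swapped$mean_close <- pc$mean_far
  swapped$mean_far <- pc$mean_close
  out_sw <- compare_close_far(swapped)
  expect_equal(out_sw$test$statistic, -out$test$statistic)
  # identical groups: t = 0, p = 1
  same <- pc; same$mean_far <- same$mean_close
  out_same <- compare_close_far(same, test = "paired")
  expect_true(is.nan(out_same$test$statistic) ||
                abs(out_same$test$statistic) < 1e-12)
  # constructed separation drives p down as the offset grows
  sep <- pc; sep$mean_close <- sep$mean_far + 0.05
  expect_lt(compare_close_far(sep)$test$p_value, 1e-10)
  expect_error(compare_close_far(pc[1, ]), "at least 2")
})

test_that("welch and paired variants are selectable", {
  withr::with_seed(74, {
    pc <- tibble::tibble(complex_id = paste0("c", 1:10),
                         mean_close = rnorm(10, 0.1, 0.02),
                         mean_far = rnorm(10, 0.08, 0.005),
                         n_close = 5L, n_far = 5L, defined = TRUE)
  })
  w <- compare_close_far(pc, test = "welch")
  p <- compare_close_far(pc, test = "paired")
  expect_equal(w$test$p_value,
               t.test(pc$mean_close, pc$mean_far)$p.value)
  expect_equal(p$test$p_value,
               t.test(pc$mean_close, pc$mean_far, paired = TRUE)$p.value)
})

test_that("interpretation results are invariant under complex relabeling", {
  # permuting the order of complexes (and their maps with them) must not
  # change the group comparison
  rep_ <- small_repertoire()
  ds <- rep_$positives
  truth <- rep_$truth$records
  rows <- truth$row[truth$has_motif & truth$motif_start == 4][1:8]
  complexes <- ds[rows, ]
  complexes$complex_id <- paste0("cx", 1:8)
  dms <- lapply(1:8, function(i) {
    generate_structure_fixture(complexes[i, ], motif_start = 4,
                               motif_length = 3,
                               complex_id = complexes$complex_id[i],
                               seed = 200 + i)
  })
  names(dms) <- complexes$complex_id
  spec <- fit_padding_spec(ds, mode = "concat_then_pad")
  cfg <- attention_config(embed_dim = 16, n_heads = 2, dropout = 0)
  model <- structure(list(
    model = "attention",
    params = tcrpred:::att_init(spec, cfg, seed = 3),
    model_config = cfg, spec = spec,
    history = tibble::tibble(), best_epoch = 0L,
    best_val_roc_auc = NA_real_, alphabet = aa_alphabet()),
    class = "tcr_model")
  r1 <- run_interpretation(model, complexes, dms)
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  r2 <- run_interpretation(model, complexes[perm, ], dms)
  expect_equal(sort(r1$per_complex$mean_close),
               sort(r2$per_complex$mean_close), tolerance = 1e-12)
  expect_equal(r1$test$p_value, r2$test$p_value, tolerance = 1e-9)
  # an untrained model still produces a well-formed report
  expect_s3_class(r1, "structure_comparison")
  expect_equal(nrow(r1$per_complex), 8L)
})

test_that("interpretation requires concat-mode models and matching shapes", {
  rep_ <- small_repertoire()
  ds <- rep_$positives[1:4, ]
  spec_pad <- fit_padding_spec(ds)
  cfg <- attention_config(embed_dim = 16, n_heads = 2)
  model_pad <- structure(list(
    model = "attention", params = tcrpred:::att_init(spec_pad, cfg, 1),
    model_config = cfg, spec = spec_pad, history = tibble::tibble(),
    best_epoch = 0L, best_val_roc_auc = NA_real_,
    alphabet = aa_alphabet()), class = "tcr_model")
  ds$complex_id <- paste0("c", 1:4)
  expect_error(run_interpretation(model_pad, ds, list()),
               "concat_then_pad")
})
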