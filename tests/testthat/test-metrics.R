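test_that("the worked example gives ROC-AUC 0.75 and all cutoff metrics 0.5", {
  labels <- c(1, 1, 0, 0)
  scores <- c(0.9, 0.4, 0.6, 0.1)
  expect_equal(roc_auc(labels, scores), 0.75)  # 3 of 4 pairs concordant
  cm <- confusion_metrics(labels, scores, cutoff = 0.5)
  expect_equal(cm$tp, 1L); expect_equal(cm$fn, 1L)
  expect_equal(cm$fp, 1L); expect_equal(cm$tn, 1L)
  expect_equal(cm$accuracy, 0.5)
  expect_equal(cm$precision, 0.5)
  expect_equal(cm$recall, 0.5)
  expect_equal(cm$specificity, 0.5)
  expect_equal(cm$f1, 0.5)
})

test_that("perfect and degenerate scores behave at the boundaries", {
  labels <- c(1, 1, 0, 0)
  expect_equal(roc_auc(labels, c(0.9, 0.8, 0.2, 0.1)), 1)
  cm <- confusion_metrics(labels, c(0.9, 0.8, 0.2, 0.1))
  expect_true(all(c(cm$accuracy, cm$precision, cm$recall,
                    cm$specificity, cm$f1) == 1))
  # all-negative calls: precision undefined-flagged, specificity 1
  cm0 <- confusion_metrics(labels, c(0.1, 0.2, 0.3, 0.2), cutoff = 0.5)
  expect_true(is.nan(cm0$precision))
  expect_true("precision" %in% cm0$undefined[[1]])
  expect_equal(cm0$specificity, 1)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
  expect_error(confusion_metrics(numeric(0), numeric(0)), "empty")
})

test_that("ROC-AUC and PR-AUC match brute-force computation on fuzzed inputs", {
  withr::with_seed(1009, {
    for (rep_i in 1:250) {
      n <- sample(4:60, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      # tied scores with some probability, to exercise the tie conventions
      scores <- if (rep_i %% 3 == 0) {
        sample(seq(0, 1, by = 0.25), n, replace = TRUE)
      } else {
        runif(n)
      }
      expect_equal(roc_auc(labels, scores), roc_auc_brute(labels, scores),
                   tolerance = 1e-12)
      expect_equal(pr_auc(labels, scores), pr_auc_brute(labels, scores),
                   tolerance = 1e-12)
    }
  })
})

test_that("confusion counts partition the set on fuzzed inputs", {
  withr::with_seed(2027, {
    for (i in 1:250) {
      n <- sample(3:50, 1)
      labels <- sample(0:1, n, replace = TRUE)
      scores <- round(runif(n), 2)
      cutoff <- runif(1)
      cm <- confusion_metrics(labels, scores, cutoff)
      expect_equal(cm$tp + cm$tn + cm$fp + cm$fn, n)
      expect_equal(cm$tp, sum(labels == 1 & scores >= cutoff))
      expect_equal(cm$tn, sum(labels == 0 & scores < cutoff))
      expect_equal(cm$accuracy, (cm$tp + cm$tn) / n)
    }
  })
})

test_that("ROC-AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    labels <- sample(0:1, 200, replace = TRUE)
    labels[1:2] <- 0:1
    scores <- runif(200)
  })
  ours <- roc_auc(labels, scores)
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("random scores on balanced labels give ROC-AUC near one half", {
  withr::with_seed(99, {
    labels <- rep(0:1, each = 5000)
    scores <- runif(10000)
  })
  expect_equal(roc_auc(labels, scores), 0.5, tolerance = 0.02)
})

test_that("per-peptide AUC flags single-class peptides and attaches counts", {
  labels <- c(1, 0, 1, 0, 1, 1)
  scores <- c(0.9, 0.1, 0.8, 0.2, 0.7, 0.6)
  peptides <- c("A", "A", "B", "B", "C", "C")
  pp <- per_peptide_auc(labels, scores, peptides)
  expect_equal(pp$roc_auc[pp$peptide == "A"], 1)
  expect_equal(pp$roc_auc[pp$peptide == "B"], 1)
  expect_true(is.na(pp$roc_auc[pp$peptide == "C"]))
  expect_false(pp$defined[pp$peptide == "C"])
  expect_equal(pp$n_pos[pp$peptide == "C"], 2L)
})

test_that("pooled AUC differs from mean per-peptide AUC in general", {
  # within each peptide scores separate perfectly, but the peptides use
  # disjoint score ranges, so pooling breaks the ordering
  labels <- c(1, 0, 1, 0)
  scores <- c(0.9, 0.8, 0.3, 0.2)
  peptides <- c("A", "A", "B", "B")
  pp <- per_peptide_auc(labels, scores, peptides)
  expect_true(all(pp$roc_auc == 1))
  expect_lt(roc_auc(labels, scores), 1)
})

test_that("Levenshtein distance matches exhaustive recursion", {
  expect_equal(levenshtein("AAA", "AAA"), 0L)
  expect_equal(levenshtein("A", ""), 1L)
  expect_equal(levenshtein("KITTEN", "SITTING"), 3L)
  withr::with_seed(17, {
    for (i in 1:25) {
      a <- paste(sample(c("A", "C", "G"), sample(0:6, 1), replace = TRUE),
                 collapse = "")
      b <- paste(sample(c("A", "C", "G"), sample(0:6, 1), replace = TRUE),
                 collapse = "")
      expect_equal(levenshtein(a, b), lev_rec(a, b))
    }
  })
})

test_that("Lmin is the minimum over the training set", {
  expect_equal(lmin("AAAA", c("AAAA", "CCCC")), 0L)
  expect_equal(lmin("AAAT", "AAAA"), 1L)
  expect_error(lmin("AAAA", character(0)), "empty")
  withr::with_seed(23, {
    train <- replicate(8, paste(sample(aa_alphabet(), 5, replace = TRUE),
                                collapse = ""))
    test <- replicate(4, paste(sample(aa_alphabet(), 5, replace = TRUE),
                               collapse = ""))
  })
  lm <- lmin(test, train)
  for (i in seq_along(test)) {
    expect_equal(lm[i], min(levenshtein(rep(test[i], 8), train)))
    expect_true(all(lm[i] <= utils::adist(test[i], train)))
  }
})

test_that("Lmin/AUC summary groups extremes correctly", {
  pp <- tibble::tibble(
    peptide = c("AAAA", "AAAC", "WWWW", "WWWY"),
    roc_auc = c(0.9, 0.8, 0.5, 0.6),
    n_pos = 5L, n_neg = 5L, defined = TRUE)
  train <- c("AAAA", "AAAD")
  out <- lmin_auc_summary(pp, train)
  expect_equal(out$min_lmin, 0L)          # AAAA itself in training
  expect_equal(out$mean_auc_min_lmin, 0.9)
  expect_equal(out$max_lmin, 4L)
  expect_equal(out$mean_auc_max_lmin, mean(c(0.5, 0.6)))
  expect_equal(out$gap, 0.9 - 0.55)
  # all peptides at the same Lmin: the two means coincide
  pp2 <- pp; pp2$peptide <- c("CAAA", "GAAA", "DAAA", "WAAA")
  out2 <- lmin_auc_summary(pp2, "AAAA")
  expect_equal(out2$mean_auc_min_lmin, out2$mean_auc_max_lmin)
})

test_that("metric report combines threshold-free and cutoff metrics", {
  labels <- c(1, 1, 0, 0)
  scores <- c(0.9, 0.4, 0.6, 0.1)
  rep_ <- metric_report(labels, scores, peptides = c("A", "A", "A", "A"))
  expect_equal(rep_$roc_auc, 0.75)
  expect_equal(rep_$accuracy, 0.5)
  expect_equal(nrow(rep_$per_peptide[[1]]), 1L)
})
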