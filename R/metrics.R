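# Binary-classifier evaluation: ROC-AUC, PR-AUC, cutoff metrics,
# per-peptide AUC, and Levenshtein-based train/test peptide similarity.

#' ROC-AUC (Mann-Whitney form)
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, with ties counting one half — computed from midranks,
#' which is exactly the normalized Mann-Whitney U statistic.
#'
#' @param labels Binary vector (1 = positive).
#' @param scores Numeric scores.
#' @return ROC-AUC in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))  # 0.75
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC-AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' PR-AUC (average precision)
#'
#' Area under the precision-recall curve by step-wise integration: the
#' average-precision form, summing precision at each positive-revealing
#' threshold weighted by the recall increment. Tied scores are treated as
#' a single threshold.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in \[0, 1\].
#' @export
pr_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1)
  if (n_pos == 0L || all(labels == 1)) {
    stop("PR-AUC undefined: both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab == 1)
  n_called <- seq_along(lab)
  # collapse tied scores to one operating point (the last index of each tie)
  keep <- c(diff(sc) != 0, TRUE)
  tp <- tp[keep]; n_called <- n_called[keep]
  precision <- tp / n_called
  recall <- tp / n_pos
  sum(precision * diff(c(0, recall)))
}

#' Confusion-matrix metrics at a cutoff
#'
#' Thresholds scores at `cutoff` (score >= cutoff is a positive call) and
#' reports accuracy, precision, specificity, recall, and F1:
#' accuracy = (TP+TN)/(TP+FN+TN+FP), precision = TP/(TP+FP),
#' specificity = TN/(FP+TN), recall = TP/(TP+FN),
#' F1 = 2 * precision * recall / (precision + recall).
#' A zero denominator yields `NaN` with the metric named in the
#' `undefined` field rather than a silent 0.
#'
#' @inheritParams roc_auc
#' @param cutoff Decision threshold, default 0.5.
#' @return A one-row tibble with counts (`tp`, `tn`, `fp`, `fn`), the
#'   five metrics, `cutoff`, and an `undefined` list-column naming any
#'   zero-denominator metrics.
#' @export
confusion_metrics <- function(labels, scores, cutoff = 0.5) {
  stopifnot(length(labels) == length(scores))
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  call_pos <- scores >= cutoff
  tp <- sum(call_pos & labels == 1)
  fp <- sum(call_pos & labels == 0)
  tn <- sum(!call_pos & labels == 0)
  fn <- sum(!call_pos & labels == 1)
  safe_div <- function(num, den) if (den == 0) NaN else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, fp + tn)
  f1 <- if (is.nan(precision) || is.nan(recall) ||
            (precision + recall) == 0) NaN else {
    2 * precision * recall / (precision + recall)
  }
  metrics <- c(accuracy = (tp + tn) / (tp + tn + fp + fn),
               precision = precision, specificity = specificity,
               recall = recall, f1 = f1)
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = metrics[["accuracy"]], precision = metrics[["precision"]],
    specificity = metrics[["specificity"]], recall = metrics[["recall"]],
    f1 = metrics[["f1"]], cutoff = cutoff,
    undefined = list(names(metrics)[is.nan(metrics)])
  )
}

#' Full metric report
#'
#' ROC-AUC, PR-AUC, and the cutoff metrics in one tibble; optionally
#' per-peptide ROC-AUC as an attached tibble.
#'
#' @inheritParams confusion_metrics
#' @param peptides Optional peptide per record for the per-peptide
#'   breakdown.
#' @return A one-row tibble; if `peptides` is given, the per-peptide
#'   table is in `attr(, "per_peptide")` and as the `per_peptide`
#'   list-column.
#' @export
metric_report <- function(labels, scores, cutoff = 0.5, peptides = NULL) {
  out <- confusion_metrics(labels, scores, cutoff)
  out <- tibble::add_column(out,
                            roc_auc = roc_auc(labels, scores),
                            pr_auc = pr_auc(labels, scores),
                            .before = 1L)
  if (!is.null(peptides)) {
    pp <- per_peptide_auc(labels, scores, peptides)
    out$per_peptide <- list(pp)
    attr(out, "per_peptide") <- pp
  }
  out
}

#' Per-peptide ROC-AUC
#'
#' ROC-AUC computed within each peptide's records. Peptides whose records
#' are single-class get `NA` with `defined = FALSE`; positive counts are
#' attached so performance can be related to peptide frequency.
#'
#' @inheritParams roc_auc
#' @param peptides Peptide of each record.
#' @return Tibble with columns `peptide`, `roc_auc`, `n_pos`, `n_neg`,
#'   `defined`, sorted by decreasing `n_pos`.
#' @export
per_peptide_auc <- function(labels, scores, peptides) {
  stopifnot(length(labels) == length(scores),
            length(labels) == length(peptides))
  groups <- split(seq_along(labels), peptides)
  rows <- lapply(names(groups), function(p) {
    i <- groups[[p]]
    np <- sum(labels[i] == 1); nn <- sum(labels[i] == 0)
    ok <- np > 0 && nn > 0
    tibble::tibble(
      peptide = p,
      roc_auc = if (ok) roc_auc(labels[i], scores[i]) else NA_real_,
      n_pos = np, n_neg = nn, defined = ok
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$n_pos), , drop = FALSE]
}

#' Levenshtein edit distance
#'
#' Minimum number of single-character substitutions, insertions, and
#' deletions transforming one sequence into the other.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Integer vector of distances.
#' @export
#' @examples
#' levenshtein("KITTEN", "SITTING")  # 3
levenshtein <- function(a, b) {
  as.integer(diag(utils::adist(a, b)))
}

#' Minimum distance from test peptides to a training peptide set
#'
#' `Lmin` of a test peptide is its minimum Levenshtein distance to any
#' training-set peptide: a train/test similarity measure. Peptides seen
#' in training have `Lmin = 0`.
#'
#' @param test_peptides Character vector of test peptides.
#' @param train_peptides Non-empty character vector of training peptides.
#' @return Integer vector, one `Lmin` per test peptide.
#' @export
lmin <- function(test_peptides, train_peptides) {
  if (length(train_peptides) == 0L) {
    stop("training peptide set is empty", call. = FALSE)
  }
  d <- utils::adist(test_peptides, unique(train_peptides))
  as.integer(apply(d, 1L, min))
}

#' Relate per-peptide AUC to train/test peptide similarity
#'
#' Compares the mean per-peptide ROC-AUC of the test peptides attaining
#' the maximum `Lmin` (least similar to training) with that of the
#' peptides attaining the minimum `Lmin` (most similar). A positive
#' difference (min-Lmin mean above max-Lmin mean) indicates that
#' similarity to training peptides drives predictive performance.
#'
#' @param per_peptide Tibble from [per_peptide_auc()] (test peptides).
#' @param train_peptides Character vector of training peptides.
#' @return List with the `lmin` table (per peptide), `min_lmin`,
#'   `max_lmin`, `mean_auc_min_lmin`, `mean_auc_max_lmin`, and `gap`
#'   (min-Lmin mean minus max-Lmin mean).
#' @export
lmin_auc_summary <- function(per_peptide, train_peptides) {
  pp <- per_peptide[per_peptide$defined, , drop = FALSE]
  if (nrow(pp) == 0L) stop("no peptides with defined AUC", call. = FALSE)
  lm <- lmin(pp$peptide, train_peptides)
  tab <- tibble::add_column(pp, lmin = lm)
  lo <- min(lm); hi <- max(lm)
  m_lo <- mean(tab$roc_auc[tab$lmin == lo])
  m_hi <- mean(tab$roc_auc[tab$lmin == hi])
  list(table = tab, min_lmin = lo, max_lmin = hi,
       mean_auc_min_lmin = m_lo, mean_auc_max_lmin = m_hi,
       gap = m_lo - m_hi)
}
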