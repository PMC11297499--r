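# Attention-vs-structure analysis: classify residue pairs by distance,
# compare mean attention scores of close vs far pairs across complexes,
# and test the difference.

#' Classify residue pairs by distance
#'
#' Labels every (peptide, CDR-beta) residue pair by strict thresholds:
#' `close` below `close_threshold`, `far` above `far_threshold`, and
#' `intermediate` otherwise (excluded from the close/far comparison).
#'
#' @param dm A `distance_map`.
#' @param close_threshold,far_threshold Angstrom thresholds (defaults 10
#'   and 25).
#' @return Object of class `pair_classification`: character matrix of
#'   labels plus the thresholds.
#' @export
classify_pairs <- function(dm, close_threshold = 10, far_threshold = 25) {
  stopifnot(close_threshold < far_threshold)
  lab <- matrix("intermediate", nrow(dm$d), ncol(dm$d))
  lab[dm$d < close_threshold] <- "close"
  lab[dm$d > far_threshold] <- "far"
  structure(list(labels = lab, close_threshold = close_threshold,
                 far_threshold = far_threshold,
                 complex_id = dm$complex_id),
            class = "pair_classification")
}

#' Mean attention score of close and far pairs for one complex
#'
#' @param scores Numeric matrix of attention scores, same shape as the
#'   classification.
#' @param cls A `pair_classification`.
#' @return One-row tibble with `mean_close`, `mean_far`, pair counts, and
#'   `defined` flags (a class with zero pairs yields `NA`).
#' @export
complex_mean_scores <- function(scores, cls) {
  if (!all(dim(scores) == dim(cls$labels))) {
    stop("score matrix ", paste(dim(scores), collapse = "x"),
         " does not match classification ",
         paste(dim(cls$labels), collapse = "x"), call. = FALSE)
  }
  close_v <- scores[cls$labels == "close"]
  far_v <- scores[cls$labels == "far"]
  tibble::tibble(
    complex_id = cls$complex_id,
    mean_close = if (length(close_v)) mean(close_v) else NA_real_,
    mean_far = if (length(far_v)) mean(far_v) else NA_real_,
    n_close = length(close_v), n_far = length(far_v),
    defined = length(close_v) > 0 && length(far_v) > 0
  )
}

#' Compare close-pair and far-pair attention scores across complexes
#'
#' Group statistics (mean and SD over complexes) of the per-complex mean
#' attention scores for close and far pairs, with a t-test for the
#' difference. The default is the unpaired two-sample Student's test
#' (equal variances); `"welch"` and `"paired"` variants are selectable,
#' since per-complex close/far means also admit a paired design.
#'
#' @param per_complex Tibble of per-complex means (rows from
#'   [complex_mean_scores()]).
#' @param test `"student"`, `"welch"`, or `"paired"`.
#' @return Object of class `structure_comparison`: per-complex table,
#'   group stats, and the test (statistic, df, p-value, variant).
#' @export
compare_close_far <- function(per_complex, test = c("student", "welch",
                                                    "paired")) {
  test <- match.arg(test)
  ok <- per_complex[per_complex$defined, , drop = FALSE]
  if (nrow(ok) < 2L) {
    stop("need at least 2 complexes with both means defined", call. = FALSE)
  }
  ht <- switch(test,
    student = stats::t.test(ok$mean_close, ok$mean_far, var.equal = TRUE),
    welch = stats::t.test(ok$mean_close, ok$mean_far, var.equal = FALSE),
    paired = stats::t.test(ok$mean_close, ok$mean_far, paired = TRUE)
  )
  structure(
    list(per_complex = ok,
         group_stats = tibble::tibble(
           group = c("close", "far"),
           mean = c(mean(ok$mean_close), mean(ok$mean_far)),
           sd = c(stats::sd(ok$mean_close), stats::sd(ok$mean_far)),
           n = nrow(ok)),
         test = list(variant = test,
                     statistic = unname(ht$statistic),
                     df = unname(ht$parameter),
                     p_value = ht$p.value)),
    class = "structure_comparison"
  )
}

#' @export
print.structure_comparison <- function(x, ...) {
  g <- x$group_stats
  cat("<structure_comparison> over", g$n[1], "complexes\n")
  cat(sprintf("  close pairs: %.4f +/- %.4f\n", g$mean[1], g$sd[1]))
  cat(sprintf("  far pairs:   %.4f +/- %.4f\n", g$mean[2], g$sd[2]))
  cat(sprintf("  %s t-test: t = %.3f, df = %.1f, p = %.3g\n",
              x$test$variant, x$test$statistic, x$test$df, x$test$p_value))
  invisible(x)
}

#' Run the attention-vs-structure analysis end to end
#'
#' For every complex: forward the (peptide, TCR) pair through a trained
#' attention model, extract the head-averaged peptide-to-CDR-beta
#' attention scores, classify residue pairs by distance, and compare the
#' per-complex close/far mean scores across the set.
#'
#' The model must have been trained with a `concat_then_pad` padding
#' spec, so real CDR-beta chain positions align with the distance-map
#' columns.
#'
#' @param model A fitted attention `tcr_model`.
#' @param complexes Dataset tibble, one row per complex, with a
#'   `complex_id` column.
#' @param distance_maps Named list of `distance_map`s keyed by
#'   `complex_id`.
#' @param close_threshold,far_threshold Angstrom thresholds.
#' @param test t-test variant, see [compare_close_far()].
#' @return A `structure_comparison`; per-complex score matrices are in
#'   `attr(, "score_maps")`.
#' @export
run_interpretation <- function(model, complexes, distance_maps,
                               close_threshold = 10, far_threshold = 25,
                               test = "student") {
  stopifnot(inherits(model, "tcr_model"), model$model == "attention")
  if (model$spec$mode != "concat_then_pad") {
    stop("interpretation requires a model trained in concat_then_pad mode",
         call. = FALSE)
  }
  pred <- predict(model, complexes, type = "maps")
  rows <- vector("list", nrow(complexes))
  score_maps <- list()
  for (i in seq_len(nrow(complexes))) {
    id <- complexes$complex_id[i]
    dm <- distance_maps[[id]]
    if (is.null(dm)) stop("no distance map for complex ", id, call. = FALSE)
    sc <- pred$maps[[i]]
    if (!all(dim(sc) == dim(dm$d))) {
      stop("complex ", id, ": score matrix ",
           paste(dim(sc), collapse = "x"),
           " does not match distance map ",
           paste(dim(dm$d), collapse = "x"), call. = FALSE)
    }
    cls <- classify_pairs(dm, close_threshold, far_threshold)
    rows[[i]] <- complex_mean_scores(sc, cls)
    score_maps[[id]] <- sc
  }
  out <- compare_close_far(dplyr::bind_rows(rows), test = test)
  attr(out, "score_maps") <- score_maps
  out
}
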