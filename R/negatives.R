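# Negative-pair generation and per-peptide down-sampling.

tcr_key <- function(d) {
  do.call(paste, c(d[cdr_slots()], sep = "|"))
}

pair_key <- function(d) {
  paste(d$peptide, tcr_key(d), sep = "||")
}

#' Generate negatives by within-partition shuffling
#'
#' For every positive pair (peptide p, TCR t) in one data partition, draws
#' up to `ratio` TCRs that bind *other* peptides of the same partition and
#' pairs them with p as label-0 records. Shuffling within a partition is
#' essential: shuffling across partitions lets a training positive TCR
#' reappear as a test negative, biasing evaluation.
#'
#' Guards: a generated negative may never duplicate a positive pair
#' present anywhere in the full dataset (exact-pair false-negative guard),
#' and negatives are deduplicated. A TCR may serve as a negative for
#' several peptides; within one positive's draw TCRs are sampled without
#' replacement. If a peptide's partition lacks enough eligible distinct
#' TCRs to meet the ratio, the shortfall is warned about and under-sampled
#' by default, or raised as an error with `strict = TRUE` — small
#' peptide-disjoint partitions routinely cannot reach the target ratio.
#'
#' @param fold_data Positive records of a single partition.
#' @param ratio Negatives per positive (positive integer).
#' @param seed Integer seed.
#' @param all_positives Positive records of the full dataset, used for the
#'   false-negative guard; defaults to `fold_data`.
#' @param strict Error instead of warning when the ratio cannot be met.
#' @return Tibble of negative records (`binder = 0`,
#'   `origin = "shuffled_negative"`), same partition as the input.
#' @export
shuffle_negatives <- function(fold_data, ratio = 5L, seed,
                              all_positives = fold_data, strict = FALSE) {
  stopifnot(ratio >= 1L, all(fold_data$binder == 1L))
  if (nrow(fold_data) == 0L) return(fold_data[0L, , drop = FALSE])
  pos_keys <- unique(pair_key(all_positives))
  tcrs <- fold_data[cdr_slots()]
  tkey <- tcr_key(fold_data)
  withr::with_seed(seed, {
    out <- vector("list", nrow(fold_data))
    seen <- character(0)
    # peptides of each TCR key within this partition (cross-reactivity aware)
    peps_of_tcr <- lapply(split(fold_data$peptide, tkey), unique)
    for (i in seq_len(nrow(fold_data))) {
      p <- fold_data$peptide[i]
      # TCRs binding *other* peptides only
      eligible_keys <- names(peps_of_tcr)[
        !vapply(peps_of_tcr, function(ps) p %in% ps, logical(1))]
      if (length(eligible_keys)) {
        # drop TCRs whose pairing with p is a known positive, and pairs
        # already emitted
        cand <- paste(p, eligible_keys, sep = "||")
        eligible_keys <- eligible_keys[!cand %in% pos_keys &
                                         !cand %in% seen]
      }
      take <- min(ratio, length(eligible_keys))
      if (take < ratio) {
        msg <- paste0("peptide ", p, ": only ", take, " of ", ratio,
                      " shuffled negatives available in its partition")
        if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
      }
      if (take == 0L) { out[[i]] <- NULL; next }
      drawn <- sample(eligible_keys, take)
      seen <- c(seen, paste(p, drawn, sep = "||"))
      rows <- match(drawn, tkey)
      neg <- tcrs[rows, , drop = FALSE]
      neg$peptide <- p
      out[[i]] <- neg
    }
    neg <- dplyr::bind_rows(out)
  })
  if (nrow(neg) == 0L) return(empty_negative_tibble(fold_data))
  finish_negatives(neg, fold_data, origin = "shuffled_negative")
}

#' Generate negatives from a control pool
#'
#' For every positive pair, draws `ratio` TCRs from a background pool of
#' unlabeled control TCRs (healthy-donor repertoire) and pairs them with
#' the positive's peptide as label-0 records. Within one positive's draw,
#' sampling is without replacement; the pool must be large enough.
#'
#' @param fold_data Positive records of a single partition.
#' @param pool Control-pool tibble (see [read_control_pool()]).
#' @param ratio Negatives per positive.
#' @param seed Integer seed.
#' @return Tibble of negative records (`origin = "control_negative"`).
#' @export
control_negatives <- function(fold_data, pool, ratio = 1L, seed) {
  stopifnot(ratio >= 1L, all(fold_data$binder == 1L), nrow(pool) > 0L)
  if (nrow(pool) < ratio) {
    stop("control pool of size ", nrow(pool),
         " cannot supply ", ratio, " negatives per positive without replacement",
         call. = FALSE)
  }
  # one draw per peptide, without replacement across that peptide's
  # requirement: counts are exact and no duplicate pairs arise
  n_per_pep <- table(fold_data$peptide) * ratio
  if (any(n_per_pep > nrow(pool))) {
    stop("control pool of size ", nrow(pool), " cannot supply ",
         max(n_per_pep), " negatives for one peptide without replacement",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    out <- lapply(names(n_per_pep), function(p) {
      rows <- sample.int(nrow(pool), n_per_pep[[p]])
      neg <- pool[rows, cdr_slots(), drop = FALSE]
      neg$peptide <- p
      neg
    })
    neg <- dplyr::bind_rows(out)
  })
  finish_negatives(neg, fold_data, origin = "control_negative")
}

#' Generate mixed negatives (shuffling + controls)
#'
#' The mixed recipe: shuffled negatives at one ratio plus control-pool
#' negatives at another (e.g. 1:3 shuffling + 1:2 controls for a combined
#' 1:5). Either component ratio may be 0, degenerating to the other
#' strategy alone. The `origin` column partitions the output exactly into
#' the two component sets.
#'
#' @inheritParams control_negatives
#' @param shuffle_ratio,control_ratio Component ratios (non-negative).
#' @param all_positives Full-dataset positives for the shuffle guard.
#' @param strict Passed to [shuffle_negatives()].
#' @return Tibble of negatives with `origin` in
#'   `c("shuffled_negative", "control_negative")`.
#' @export
mixed_negatives <- function(fold_data, pool, shuffle_ratio = 3L,
                            control_ratio = 2L, seed,
                            all_positives = fold_data, strict = FALSE) {
  stopifnot(shuffle_ratio >= 0L, control_ratio >= 0L,
            shuffle_ratio + control_ratio >= 1L)
  parts <- list()
  if (shuffle_ratio > 0L) {
    parts$sh <- shuffle_negatives(fold_data, ratio = shuffle_ratio,
                                  seed = seed,
                                  all_positives = all_positives,
                                  strict = strict)
  }
  if (control_ratio > 0L) {
    parts$ct <- control_negatives(fold_data, pool, ratio = control_ratio,
                                  seed = seed + 1L)
  }
  dplyr::bind_rows(parts)
}

#' Down-sample positives to a per-peptide cap
#'
#' Balances peptide representation: for every peptide, keeps
#' `min(count, cap)` records chosen uniformly at random under the seed;
#' peptides below the cap keep all their records. The selection is
#' invariant to the input row order (records are ordered canonically
#' before sampling).
#'
#' @param data Positive records.
#' @param cap Per-peptide ceiling (>= 1), e.g. 100 for a balanced
#'   benchmark or 500 for a lightly-capped expanded set.
#' @param seed Integer seed.
#' @return Down-sampled tibble.
#' @export
balance_downsample <- function(data, cap = 100L, seed) {
  stopifnot(cap >= 1L, all(data$binder == 1L))
  ord <- order(pair_key(data))
  data <- data[ord, , drop = FALSE]
  keep <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(data)), data$peptide), function(rows) {
      if (length(rows) <= cap) rows else sample(rows, cap)
    }), use.names = FALSE)
  })
  data[sort(keep), , drop = FALSE]
}

#' Attach partition-wise negatives to a split dataset
#'
#' Convenience wrapper running one negative-sampling strategy separately
#' within every partition of an already split dataset, returning
#' positives and negatives combined.
#'
#' @param data Positive records with a filled `partition` column.
#' @param strategy `"shuffle"`, `"control"`, or `"mixed"`.
#' @param pool Control pool (for `"control"` / `"mixed"`).
#' @param ratio Shuffle or control ratio for the single-strategy modes.
#' @param shuffle_ratio,control_ratio Component ratios for `"mixed"`.
#' @param seed Integer seed (one per-partition stream is derived from it).
#' @param strict Passed to [shuffle_negatives()].
#' @return Combined tibble of positives and negatives.
#' @export
add_negatives <- function(data, strategy = c("shuffle", "control", "mixed"),
                          pool = NULL, ratio = 5L, shuffle_ratio = 3L,
                          control_ratio = 2L, seed, strict = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(!anyNA(data$partition))
  all_pos <- data[data$binder == 1L, , drop = FALSE]
  folds <- sort(unique(data$partition))
  negs <- lapply(seq_along(folds), function(fi) {
    fd <- data[data$partition == folds[fi] & data$binder == 1L, , drop = FALSE]
    fseed <- seed + 1000L * fi
    switch(strategy,
      shuffle = shuffle_negatives(fd, ratio = ratio, seed = fseed,
                                  all_positives = all_pos, strict = strict),
      control = control_negatives(fd, pool, ratio = ratio, seed = fseed),
      mixed = mixed_negatives(fd, pool, shuffle_ratio = shuffle_ratio,
                              control_ratio = control_ratio, seed = fseed,
                              all_positives = all_pos, strict = strict)
    )
  })
  dplyr::bind_rows(c(list(data), negs))
}

finish_negatives <- function(neg, fold_data, origin) {
  neg$binder <- 0L
  neg$partition <- fold_data$partition[1L]
  neg$origin <- origin
  cols <- intersect(.dataset_cols, names(neg))
  out <- neg[cols]
  class(out) <- c("tcr_dataset", class(tibble::tibble()))
  out
}

empty_negative_tibble <- function(fold_data) {
  out <- fold_data[0L, , drop = FALSE]
  out
}
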