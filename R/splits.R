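# Fold splitting, nested cross-validation plan, and leakage audits.

#' Random k-fold split of positive records
#'
#' Assigns records to k folds of near-equal size (sizes differ by at most
#' one), uniformly at random under the seed. Used for the seen-epitope
#' evaluation regime, where the same peptide may occur in several folds.
#'
#' @param data Dataset tibble of positive records.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; equal seeds give identical assignments.
#' @return The dataset with its `partition` column filled with fold
#'   indices 0..k-1.
#' @export
random_kfold <- function(data, k = 5L, seed) {
  stopifnot(k >= 2L)
  n <- nrow(data)
  if (n < k) stop("fewer records (", n, ") than folds (", k, ")",
                  call. = FALSE)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k) - 1L, n)))
  data$partition <- folds
  data
}

#' Peptide-disjoint ("strict") k-fold split
#'
#' Shuffles the distinct peptides under the seed, deals them round-robin
#' across k folds, and assigns every record to its peptide's fold, so the
#' peptide sets of any two folds are disjoint. This is the unseen-epitope
#' evaluation regime: test-fold peptides never occur in training folds.
#' Round-robin balances peptide counts per fold, not record counts —
#' balancing records would correlate fold membership with peptide
#' frequency.
#'
#' @inheritParams random_kfold
#' @return The dataset with `partition` filled; fold peptide sets are
#'   pairwise disjoint.
#' @export
strict_split <- function(data, k = 5L, seed) {
  stopifnot(k >= 2L)
  peps <- unique(data$peptide)
  if (length(peps) < k) {
    stop("strict split needs at least k = ", k, " distinct peptides, got ",
         length(peps), call. = FALSE)
  }
  shuffled <- withr::with_seed(seed, sample(peps))
  fold_of_pep <- stats::setNames(rep_len(seq_len(k) - 1L, length(shuffled)),
                                 shuffled)
  data$partition <- unname(fold_of_pep[data$peptide])
  data
}

#' Modified nested cross-validation plan
#'
#' For k folds, produces k (test, validation, train) triples: triple i
#' tests on fold i, validates on one other fold — the cyclic successor,
#' a deterministic balanced choice — and trains on the remaining k - 2
#' folds. This is the "one inner loop, k outer loops" reduction of full
#' nested CV: each fold is the test fold exactly once, and the validation
#' fold is used only to select the training epoch.
#'
#' @param k Number of folds (>= 3).
#' @return Tibble with columns `test`, `val`, and list-column `train`.
#' @export
#' @examples
#' nested_cv_plan(5)
nested_cv_plan <- function(k = 5L) {
  if (k < 3L) stop("nested CV needs k >= 3 folds", call. = FALSE)
  folds <- seq_len(k) - 1L
  tibble::tibble(
    test = folds,
    val = (folds + 1L) %% k,
    train = lapply(folds, function(f) setdiff(folds, c(f, (f + 1L) %% k)))
  )
}

#' Audit two partitions for label leakage
#'
#' Checks the failure mode that motivates within-partition negative
#' shuffling: (a) exact (peptide, six-CDR) pairs occurring in both
#' partitions with conflicting labels — e.g. a training positive reused
#' as a test negative; (b) under `mode = "strict"`, any peptide shared
#' between the partitions at all.
#'
#' @param train,test Labeled dataset tibbles.
#' @param mode `"random"` checks only exact-pair label conflicts;
#'   `"strict"` additionally requires disjoint peptide sets.
#' @return Object of class `leakage_report`: list with `clean` flag, a
#'   tibble of `pair_conflicts`, and a character vector of
#'   `shared_peptides` (strict mode only).
#' @export
audit_leakage <- function(train, test, mode = c("random", "strict")) {
  mode <- match.arg(mode)
  key_cols <- c("peptide", cdr_slots())
  key <- function(d) do.call(paste, c(d[key_cols], sep = "|"))
  tr_key <- key(train); te_key <- key(test)
  tr_lab <- tapply(train$binder, tr_key, function(x) unique(x))
  te_lab <- tapply(test$binder, te_key, function(x) unique(x))
  shared <- intersect(names(tr_lab), names(te_lab))
  conflict <- shared[vapply(shared, function(s) {
    length(intersect(tr_lab[[s]], te_lab[[s]])) == 0L ||
      length(tr_lab[[s]]) > 1L || length(te_lab[[s]]) > 1L
  }, logical(1))]
  pair_conflicts <- tibble::tibble(
    pair = conflict,
    train_label = vapply(conflict, function(s) paste(tr_lab[[s]], collapse = "/"),
                         character(1)),
    test_label = vapply(conflict, function(s) paste(te_lab[[s]], collapse = "/"),
                        character(1))
  )
  shared_peptides <- if (mode == "strict") {
    intersect(unique(train$peptide), unique(test$peptide))
  } else character(0)
  structure(
    list(clean = nrow(pair_conflicts) == 0L && length(shared_peptides) == 0L,
         pair_conflicts = pair_conflicts,
         shared_peptides = shared_peptides,
         mode = mode),
    class = "leakage_report"
  )
}

#' @export
print.leakage_report <- function(x, ...) {
  cat("<leakage_report> mode:", x$mode,
      if (x$clean) "- clean\n" else "- LEAKAGE DETECTED\n")
  if (nrow(x$pair_conflicts)) {
    cat(nrow(x$pair_conflicts), "exact-pair label conflict(s)\n")
  }
  if (length(x$shared_peptides)) {
    cat(length(x$shared_peptides), "peptide(s) shared across partitions:",
        paste(utils::head(x$shared_peptides, 5L), collapse = ", "), "\n")
  }
  invisible(x)
}

# split a dataset by the nested-CV triple for one test fold
cv_partitions <- function(data, plan_row) {
  train_folds <- plan_row$train[[1L]]
  list(
    train = data[data$partition %in% train_folds, , drop = FALSE],
    val = data[data$partition == plan_row$val, , drop = FALSE],
    test = data[data$partition == plan_row$test, , drop = FALSE]
  )
}
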