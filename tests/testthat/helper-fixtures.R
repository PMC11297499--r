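# Shared fixtures, generated in code. The small repertoire is memoised so
# the suite builds it once.

toy_dataset <- function(n = 6L) {
  tibble::tibble(
    peptide = rep(c("GILGFVFTL", "NLVPMVATV"), length.out = n),
    A1 = "TSGFYG", A2 = "NALDGL", A3 = "CAVSESPFGNEKLTF",
    B1 = "MNHEY", B2 = "SVGAGI",
    B3 = paste0("CASSIRSSYEQ", rep(c("Y", "W", "H", "F", "L", "M"),
                                   length.out = n), "F"),
    binder = 1L, partition = NA_integer_, origin = "positive_db"
  )
}

small_repertoire <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_repertoire(
        generator_config(n_peptides = 10, tcrs_per_peptide = 50, seed = 401))
    }
    cache
  }
})

# brute-force ROC-AUC by exhaustive pair enumeration (ties count 1/2)
roc_auc_brute <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- outer(pos, neg, `>`) + 0.5 * outer(pos, neg, `==`)
  sum(wins) / (length(pos) * length(neg))
}

# brute-force average precision via per-threshold confusion counts
pr_auc_brute <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  prev_rec <- 0; ap <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(called & labels == 1)
    prec <- tp / sum(called)
    rec <- tp / n_pos
    ap <- ap + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  ap
}

# exhaustive-recursion edit distance for short strings
lev_rec <- function(a, b) {
  if (nchar(a) == 0) return(nchar(b))
  if (nchar(b) == 0) return(nchar(a))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(lev_rec(substr(a, 2, nchar(a)), b) + 1,
      lev_rec(a, substr(b, 2, nchar(b))) + 1,
      lev_rec(substr(a, 2, nchar(a)), substr(b, 2, nchar(b))) + cost)
}
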