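# Sequence encodings shared by both model families.

#' Canonical amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes in alphabetical order.
#' Token index 0 is reserved for padding; residue `i` of this vector has
#' token index `i`. The ordering is frozen here and serialized with every
#' model checkpoint so that encodings are stable across sessions.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# fast residue -> index lookup table (named integer vector)
.aa_index <- local({
  idx <- seq_len(20L)
  names(idx) <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  idx
})

#' Validate amino-acid sequences
#'
#' Checks that each string is non-empty and contains only the 20 standard
#' one-letter codes (after uppercasing).
#'
#' @param x Character vector of sequences.
#' @return Logical vector, `TRUE` where valid.
#' @export
is_valid_aa <- function(x) {
  !is.na(x) & nzchar(x) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", toupper(x))
}

#' Convert sequences to token indices
#'
#' @param x Character vector of valid amino-acid sequences.
#' @return List of integer vectors over 1..20.
#' @keywords internal
aa_tokens <- function(x) {
  lapply(strsplit(toupper(x), "", fixed = TRUE), function(ch) {
    unname(.aa_index[ch])
  })
}

# The six CDR slots plus the peptide, in canonical column order.
cdr_slots <- function() c("A1", "A2", "A3", "B1", "B2", "B3")
seq_slots <- function() c("peptide", cdr_slots())

#' Fit a padding specification from training data
#'
#' Records, per sequence slot (peptide and the six CDRs), the maximum
#' observed length plus a margin. The spec is frozen at training time and
#' carried in the model checkpoint so that test-time sequences encode to
#' the same shapes.
#'
#' @param data Dataset tibble (see [read_tcr_dataset()]).
#' @param margin Non-negative integer added to every observed maximum.
#' @param mode Chain assembly mode: `"pad_then_concat"` pads each CDR to
#'   its slot length before concatenation (training default);
#'   `"concat_then_pad"` concatenates the raw CDRs first and pads the
#'   result, the convention used for attention-map interpretation.
#' @return Object of class `padding_spec`: named list of slot lengths plus
#'   the mode and the frozen alphabet.
#' @export
fit_padding_spec <- function(data, margin = 0L,
                             mode = c("pad_then_concat", "concat_then_pad")) {
  mode <- match.arg(mode)
  stopifnot(nrow(data) > 0L, margin >= 0L)
  slots <- seq_slots()
  max_len <- vapply(slots, function(s) max(nchar(data[[s]])), integer(1))
  spec <- list(
    max_len = as.integer(max_len + margin),
    mode = mode,
    alphabet = aa_alphabet()
  )
  names(spec$max_len) <- slots
  class(spec) <- "padding_spec"
  spec
}

#' @export
print.padding_spec <- function(x, ...) {
  cat("<padding_spec> mode:", x$mode, "\n")
  print(x$max_len)
  invisible(x)
}

#' One-hot encode a sequence
#'
#' @param seq A single valid amino-acid sequence.
#' @param L Slot length; must be at least `nchar(seq)`.
#' @return A 20 x `L` binary matrix: column `i` is the indicator of
#'   residue `i`; columns beyond the sequence length are all zero (no
#'   extra padding channel).
#' @export
#' @examples
#' m <- one_hot("ACD", 4)
#' colSums(m)  # 1 1 1 0
one_hot <- function(seq, L) {
  stopifnot(length(seq) == 1L)
  if (!is_valid_aa(seq)) {
    stop("invalid amino-acid sequence: ", seq, call. = FALSE)
  }
  n <- nchar(seq)
  if (n > L) {
    stop("sequence of length ", n, " does not fit slot length ", L,
         call. = FALSE)
  }
  idx <- aa_tokens(seq)[[1L]]
  m <- matrix(0, nrow = 20L, ncol = L,
              dimnames = list(aa_alphabet(), NULL))
  m[cbind(idx, seq_len(n))] <- 1
  m
}

#' Decode a one-hot matrix back to its sequence
#'
#' @param m A 20 x L one-hot matrix as produced by [one_hot()].
#' @return The original sequence string.
#' @export
decode_one_hot <- function(m) {
  real <- colSums(m) > 0
  paste(aa_alphabet()[apply(m[, real, drop = FALSE], 2L, which.max)],
        collapse = "")
}

# Encode a character vector of sequences into a B x L integer index matrix
# (0 = pad). Workhorse for both model paths.
token_matrix <- function(seqs, L) {
  lens <- nchar(seqs)
  if (any(lens > L)) {
    stop("sequence longer than slot length ", L, ": ",
         seqs[which.max(lens)], call. = FALSE)
  }
  out <- matrix(0L, nrow = length(seqs), ncol = L)
  toks <- aa_tokens(seqs)
  for (b in seq_along(toks)) {
    n <- lens[b]
    if (n > 0L) out[b, seq_len(n)] <- toks[[b]]
  }
  out
}

#' Assemble a CDR chain token sequence
#'
#' Builds the model input for one chain from its three CDR sequences.
#' In `pad_then_concat` mode each CDR is zero-padded to its slot length
#' and the padded pieces are concatenated; in `concat_then_pad` mode the
#' raw CDRs are concatenated first and the result is padded at the end.
#' Total length is identical across records for a fixed spec, and a
#' segment map records which chain position came from which CDR.
#'
#' @param cdr1,cdr2,cdr3 CDR sequences of one chain.
#' @param spec A `padding_spec`.
#' @param chain `"A"` or `"B"`: which chain's slot lengths to use.
#' @return Object of class `token_seq`: list with integer `indices`
#'   (0 = pad), binary `mask`, and a `segment_map` tibble with one row
#'   per real position (`position`, `cdr`, `offset`).
#' @export
build_chain <- function(cdr1, cdr2, cdr3, spec, chain = c("B", "A")) {
  chain <- match.arg(chain)
  slots <- paste0(chain, 1:3)
  lens <- spec$max_len[slots]
  cdrs <- c(cdr1, cdr2, cdr3)
  n <- nchar(cdrs)
  total <- sum(lens)
  idx <- integer(total)
  toks <- aa_tokens(cdrs)
  if (spec$mode == "pad_then_concat") {
    if (any(n > lens)) {
      bad <- which(n > lens)[1L]
      stop("CDR", bad, " of length ", n[bad], " does not fit slot length ",
           lens[bad], call. = FALSE)
    }
    starts <- cumsum(c(0L, lens[-3L]))
    pos <- integer(0)
    for (i in 1:3) {
      p <- starts[i] + seq_len(n[i])
      idx[p] <- toks[[i]]
      pos <- c(pos, p)
    }
  } else {
    if (sum(n) > total) {
      stop("concatenated CDRs of length ", sum(n),
           " do not fit total length ", total, call. = FALSE)
    }
    starts <- cumsum(c(0L, n[-3L]))
    pos <- integer(0)
    for (i in 1:3) {
      p <- starts[i] + seq_len(n[i])
      idx[p] <- toks[[i]]
      pos <- c(pos, p)
    }
  }
  seg <- tibble::tibble(
    position = pos,
    cdr = rep(slots, n),
    offset = unlist(lapply(n, seq_len), use.names = FALSE)
  )
  structure(
    list(indices = idx, mask = as.integer(idx > 0L), segment_map = seg),
    class = "token_seq"
  )
}

#' Decode a chain token sequence back to its CDRs
#'
#' Inverse of [build_chain()] via the segment map.
#'
#' @param ts A `token_seq`.
#' @return Named character vector of the three CDR sequences.
#' @export
decode_chain <- function(ts) {
  ab <- aa_alphabet()
  seg <- ts$segment_map
  vapply(split(seg$position, seg$cdr), function(p) {
    paste(ab[ts$indices[p]], collapse = "")
  }, character(1))
}

# Token index matrices for a whole dataset, per model path.
#
# Returns a list with:
#   cnn: list of 7 B x L index matrices (peptide, A1..B3), for the
#        embedding-lookup formulation of the one-hot convolution
#   pep / chainA / chainB: B x L index matrices for the attention path
encode_dataset <- function(data, spec) {
  slots <- seq_slots()
  cnn <- lapply(slots, function(s) token_matrix(data[[s]], spec$max_len[[s]]))
  names(cnn) <- slots
  la <- sum(spec$max_len[c("A1", "A2", "A3")])
  lb <- sum(spec$max_len[c("B1", "B2", "B3")])
  n <- nrow(data)
  chainA <- matrix(0L, n, la)
  chainB <- matrix(0L, n, lb)
  if (spec$mode == "pad_then_concat") {
    offA <- cumsum(c(0L, spec$max_len[c("A1", "A2")]))
    offB <- cumsum(c(0L, spec$max_len[c("B1", "B2")]))
    for (i in 1:3) {
      sa <- paste0("A", i); sb <- paste0("B", i)
      chainA[, offA[i] + seq_len(spec$max_len[[sa]])] <- cnn[[sa]]
      chainB[, offB[i] + seq_len(spec$max_len[[sb]])] <- cnn[[sb]]
    }
  } else {
    toksA <- aa_tokens(paste0(data$A1, data$A2, data$A3))
    toksB <- aa_tokens(paste0(data$B1, data$B2, data$B3))
    for (b in seq_len(n)) {
      ta <- toksA[[b]]; tb <- toksB[[b]]
      if (length(ta) > la || length(tb) > lb) {
        stop("concatenated CDRs exceed chain length at record ", b,
             call. = FALSE)
      }
      chainA[b, seq_along(ta)] <- ta
      chainB[b, seq_along(tb)] <- tb
    }
  }
  list(cnn = cnn, pep = cnn$peptide, chainA = chainA, chainB = chainB)
}
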