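# Reciprocal-attention model. Three inputs — peptide, CDR-alpha chain,
# CDR-beta chain (each chain the concatenation of its three CDRs) — are
# token-embedded (plus learned positional embeddings), passed through a
# per-input multi-head self-attention layer, then through a reciprocal
# cross-attention layer with fixed wiring: the peptide queries the
# concatenated alpha+beta chain; each chain queries the peptide. Each
# branch output is flattened and projected through two fully connected
# layers; the three branch vectors are concatenated and fed to a
# two-layer sigmoid head. The reciprocal layer's peptide-as-query
# probabilities are the interpretable attention maps.

#' Attention model configuration
#'
#' @param embed_dim Embedding width; must be divisible by `n_heads`.
#' @param n_heads Attention heads.
#' @param branch_fc_dims Widths of the two per-branch fully connected
#'   layers applied to the flattened branch output.
#' @param head_dims Widths of the two head layers; last must be 1.
#' @param dropout Dropout rate on branch/head hidden layers in training.
#' @param positional Add learned positional embeddings (attention is
#'   permutation-invariant without them; CDR and peptide positions carry
#'   signal, so the default is on).
#' @param residual Residual (skip) connections: `"self"` (default) adds
#'   a skip around the self-attention layer only; `"both"` also adds one
#'   around the reciprocal layer; `"none"` disables both. The
#'   self-attention skip preserves per-position identity (without it the
#'   attention probabilities degenerate toward uniform); leaving the
#'   reciprocal layer skip-free removes an additive shortcut past the
#'   cross-attention weights, so inter-molecular information must flow
#'   through them — which is what makes the maps interpretable.
#' @return An `attention_config` list.
#' @export
attention_config <- function(embed_dim = 32L, n_heads = 4L,
                             branch_fc_dims = c(64L, 32L),
                             head_dims = c(32L, 1L), dropout = 0.3,
                             positional = TRUE,
                             residual = c("self", "both", "none")) {
  if (is.logical(residual)) residual <- if (residual) "both" else "none"
  residual <- match.arg(residual)
  stopifnot(embed_dim %% n_heads == 0L,
            utils::tail(head_dims, 1L) == 1L, length(head_dims) == 2L,
            length(branch_fc_dims) == 2L, dropout >= 0, dropout < 1)
  structure(list(embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 branch_fc_dims = as.integer(branch_fc_dims),
                 head_dims = as.integer(head_dims),
                 dropout = dropout, positional = isTRUE(positional),
                 residual = residual),
            class = "attention_config")
}

att_lengths <- function(spec) {
  list(pep = spec$max_len[["peptide"]],
       A = sum(spec$max_len[c("A1", "A2", "A3")]),
       B = sum(spec$max_len[c("B1", "B2", "B3")]))
}

att_init <- function(spec, cfg, seed) {
  d <- cfg$embed_dim
  L <- att_lengths(spec)
  withr::with_seed(seed, {
    fc1_in <- function(len) len * d
    branch_fc <- function(len) {
      list(W1 = glorot(fc1_in(len), cfg$branch_fc_dims[1]),
           b1 = numeric(cfg$branch_fc_dims[1]),
           W2 = glorot(cfg$branch_fc_dims[1], cfg$branch_fc_dims[2]),
           b2 = numeric(cfg$branch_fc_dims[2]))
    }
    list(
      # unit-variance token embeddings: with no normalization layers in
      # the architecture, smaller scales leave the attention logits near
      # zero and the softmax stuck at uniform
      emb = matrix(stats::rnorm(20L * d), 20L, d),
      pos = list(pep = matrix(stats::rnorm(L$pep * d, sd = 0.3), L$pep, d),
                 A = matrix(stats::rnorm(L$A * d, sd = 0.3), L$A, d),
                 B = matrix(stats::rnorm(L$B * d, sd = 0.3), L$B, d)),
      self_att = list(pep = mha_params(d), A = mha_params(d),
                      B = mha_params(d)),
      recip = list(pep = mha_params(d), A = mha_params(d),
                   B = mha_params(d)),
      fc = list(pep = branch_fc(L$pep), A = branch_fc(L$A),
                B = branch_fc(L$B)),
      head = list(W1 = glorot(3L * cfg$branch_fc_dims[2],
                              cfg$head_dims[1]),
                  b1 = numeric(cfg$head_dims[1]),
                  W2 = glorot(cfg$head_dims[1], 1L),
                  b2 = numeric(1L))
    )
  })
}

# embed a B x L token matrix: (B, L, d) array, pads embed to zero
att_embed <- function(params, A, pos_name, cfg) {
  B <- nrow(A); L <- ncol(A); d <- cfg$embed_dim
  E <- rbind(0, params$emb)
  X <- array(E[as.vector(A) + 1L, , drop = FALSE], c(B, L, d))
  if (cfg$positional) {
    pos_big <- outer(rep(1, B), params$pos[[pos_name]])  # (B, L, d)
    X <- X + pos_big * as.vector(A > 0L)
  }
  X
}

# zero out pad query positions of a (B, L, d) representation
# (mask recycles over the feature axis in column-major order)
mask_positions <- function(X, mask) {
  X * as.vector(mask)
}

# concatenate two (B, L, d) arrays along the position axis
cat_seq <- function(Xa, Xb) {
  B <- dim(Xa)[1]; d <- dim(Xa)[3]
  out <- array(0, c(B, dim(Xa)[2] + dim(Xb)[2], d))
  out[, seq_len(dim(Xa)[2]), ] <- Xa
  out[, dim(Xa)[2] + seq_len(dim(Xb)[2]), ] <- Xb
  out
}

# Full forward pass.
# enc: encode_dataset() result. Returns probability, caches, and the
# three reciprocal attention-probability arrays.
att_forward <- function(params, enc, cfg, training = FALSE) {
  mask <- list(pep = (enc$pep > 0L) * 1,
               A = (enc$chainA > 0L) * 1,
               B = (enc$chainB > 0L) * 1)
  if (any(rowSums(mask$pep) == 0) || any(rowSums(mask$A) == 0) ||
      any(rowSums(mask$B) == 0)) {
    stop("all-pad input sequence", call. = FALSE)
  }
  X <- list(pep = att_embed(params, enc$pep, "pep", cfg),
            A = att_embed(params, enc$chainA, "A", cfg),
            B = att_embed(params, enc$chainB, "B", cfg))
  # self-attention per input (with optional residual skip)
  res_self <- cfg$residual %in% c("self", "both")
  res_recip <- cfg$residual == "both"
  sa <- lapply(c("pep", "A", "B"), function(nm) {
    out <- mha_forward(params$self_att[[nm]], X[[nm]], X[[nm]],
                       mask[[nm]], cfg$n_heads)
    if (res_self) out$out <- out$out + X[[nm]]
    out
  })
  names(sa) <- c("pep", "A", "B")
  # reciprocal wiring: pep -> (A || B); A -> pep; B -> pep
  kvAB <- cat_seq(sa$A$out, sa$B$out)
  maskAB <- cbind(mask$A, mask$B)
  ra <- list(
    pep = mha_forward(params$recip$pep, sa$pep$out, kvAB, maskAB,
                      cfg$n_heads),
    A = mha_forward(params$recip$A, sa$A$out, sa$pep$out, mask$pep,
                    cfg$n_heads),
    B = mha_forward(params$recip$B, sa$B$out, sa$pep$out, mask$pep,
                    cfg$n_heads)
  )
  if (res_recip) {
    ra$pep$out <- ra$pep$out + sa$pep$out
    ra$A$out <- ra$A$out + sa$A$out
    ra$B$out <- ra$B$out + sa$B$out
  }
  # pad query positions carry no information forward
  O <- list(pep = mask_positions(ra$pep$out, mask$pep),
            A = mask_positions(ra$A$out, mask$A),
            B = mask_positions(ra$B$out, mask$B))
  B_n <- dim(O$pep)[1]
  fc <- list(); drops <- list()
  for (nm in c("pep", "A", "B")) {
    Flat <- matrix(O[[nm]], B_n, dim(O[[nm]])[2] * dim(O[[nm]])[3])
    p <- params$fc[[nm]]
    Z1pre <- add_bias(Flat %*% p$W1, p$b1)
    Z1 <- relu(Z1pre)
    d1 <- NULL
    if (training && cfg$dropout > 0) {
      d1 <- dropout_mask(nrow(Z1), ncol(Z1), cfg$dropout)
      Z1 <- Z1 * d1
    }
    Z2pre <- add_bias(Z1 %*% p$W2, p$b2)
    Z2 <- relu(Z2pre)
    fc[[nm]] <- list(Flat = Flat, Z1pre = Z1pre, Z1 = Z1,
                     Z2pre = Z2pre, Z2 = Z2, d1 = d1)
  }
  Xc <- cbind(fc$pep$Z2, fc$A$Z2, fc$B$Z2)
  hp <- params$head
  H1pre <- add_bias(Xc %*% hp$W1, hp$b1)
  H1 <- relu(H1pre)
  dh <- NULL
  if (training && cfg$dropout > 0) {
    dh <- dropout_mask(nrow(H1), ncol(H1), cfg$dropout)
    H1 <- H1 * dh
  }
  logit <- drop(add_bias(H1 %*% hp$W2, hp$b2))
  p_out <- sigmoid(logit)
  list(prob = p_out,
       maps = list(pep = ra$pep$cache$P, A = ra$A$cache$P,
                   B = ra$B$cache$P),
       cache = list(mask = mask, maskAB = maskAB, sa = sa, ra = ra,
                    fc = fc, Xc = Xc, H1pre = H1pre, H1 = H1, dh = dh,
                    enc = enc))
}

att_backward <- function(params, cache, dlogit, cfg) {
  hp <- params$head
  dlogit <- matrix(dlogit, ncol = 1L)
  gW2h <- crossprod(cache$H1, dlogit)
  gb2h <- sum(dlogit)
  dH1 <- dlogit %*% t(hp$W2)
  if (!is.null(cache$dh)) dH1 <- dH1 * cache$dh
  dH1 <- dH1 * (cache$H1pre > 0)
  gW1h <- crossprod(cache$Xc, dH1)
  gb1h <- colSums(dH1)
  dXc <- dH1 %*% t(hp$W1)
  Fd <- cfg$branch_fc_dims[2]
  dZ2 <- list(pep = dXc[, seq_len(Fd), drop = FALSE],
              A = dXc[, Fd + seq_len(Fd), drop = FALSE],
              B = dXc[, 2L * Fd + seq_len(Fd), drop = FALSE])
  gfc <- list(); dO <- list()
  for (nm in c("pep", "A", "B")) {
    f <- cache$fc[[nm]]; p <- params$fc[[nm]]
    dz2 <- dZ2[[nm]] * (f$Z2pre > 0)
    gW2 <- crossprod(f$Z1, dz2)
    gb2 <- colSums(dz2)
    dZ1 <- dz2 %*% t(p$W2)
    if (!is.null(f$d1)) dZ1 <- dZ1 * f$d1
    dZ1 <- dZ1 * (f$Z1pre > 0)
    gW1 <- crossprod(f$Flat, dZ1)
    gb1 <- colSums(dZ1)
    dFlat <- dZ1 %*% t(p$W1)
    gfc[[nm]] <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    B_n <- nrow(dFlat)
    Lnm <- ncol(cache$mask[[nm]])
    dO[[nm]] <- array(dFlat, c(B_n, Lnm, cfg$embed_dim))
    dO[[nm]] <- mask_positions(dO[[nm]], cache$mask[[nm]])
  }
  # reciprocal layers
  res_self <- cfg$residual %in% c("self", "both")
  res_recip <- cfg$residual == "both"
  bk_pep <- mha_backward(params$recip$pep, cache$ra$pep$cache, dO$pep)
  bk_A <- mha_backward(params$recip$A, cache$ra$A$cache, dO$A)
  bk_B <- mha_backward(params$recip$B, cache$ra$B$cache, dO$B)
  LA <- ncol(cache$mask$A)
  dSA <- list(
    pep = grad_add(bk_A$dXk, bk_B$dXk),
    A = bk_pep$dXk[, seq_len(LA), , drop = FALSE],
    B = bk_pep$dXk[, LA + seq_len(ncol(cache$mask$B)), , drop = FALSE]
  )
  dSA$pep <- grad_add(dSA$pep, bk_pep$dXq)
  dSA$A <- grad_add(dSA$A, bk_A$dXq)
  dSA$B <- grad_add(dSA$B, bk_B$dXq)
  if (res_recip) {
    # the reciprocal residual passes dO straight to the self-attention
    # outputs (query side)
    dSA$pep <- grad_add(dSA$pep, dO$pep)
    dSA$A <- grad_add(dSA$A, dO$A)
    dSA$B <- grad_add(dSA$B, dO$B)
  }
  # self-attention layers (query and key/value are the same tensor)
  gsa <- list(); dX <- list()
  for (nm in c("pep", "A", "B")) {
    bk <- mha_backward(params$self_att[[nm]], cache$sa[[nm]]$cache,
                       dSA[[nm]])
    gsa[[nm]] <- bk$grads
    dX[[nm]] <- grad_add(bk$dXq, bk$dXk)
    if (res_self) dX[[nm]] <- grad_add(dX[[nm]], dSA[[nm]])
  }
  # embeddings
  d <- cfg$embed_dim
  gemb <- matrix(0, 20L, d)
  gpos <- list()
  for (nm in c("pep", "A", "B")) {
    A_idx <- switch(nm, pep = cache$enc$pep, A = cache$enc$chainA,
                    B = cache$enc$chainB)
    L <- ncol(A_idx)
    gp <- matrix(0, L, d)
    for (l in seq_len(L)) {
      dxl <- matrix(dX[[nm]][, l, ], nrow(A_idx), d)
      g <- rowsum(dxl, group = A_idx[, l])
      idx <- as.integer(rownames(g))
      keep <- idx > 0L
      gemb[idx[keep], ] <- gemb[idx[keep], ] + g[keep, , drop = FALSE]
      if (cfg$positional) {
        real <- A_idx[, l] > 0L
        gp[l, ] <- colSums(dxl[real, , drop = FALSE])
      }
    }
    gpos[[nm]] <- gp
  }
  list(emb = gemb, pos = gpos,
       self_att = gsa,
       recip = list(pep = bk_pep$grads, A = bk_A$grads, B = bk_B$grads),
       fc = gfc,
       head = list(W1 = gW1h, b1 = gb1h, W2 = gW2h, b2 = gb2h))
}

#' Extract peptide-to-CDR-beta attention scores
#'
#' From the reciprocal layer's peptide-as-query attention map, extracts
#' the CDR-beta block of the key axis, aggregates over heads (arithmetic
#' mean by default), and drops pad rows and columns, giving a
#' real-residue score matrix of shape |peptide| x |CDR-beta|.
#'
#' @param maps The `maps` element of an attention forward pass.
#' @param enc The encoding the forward pass used.
#' @param record Record index within the batch.
#' @param aggregation `"mean"` over heads, or a head index.
#' @return Numeric matrix, peptide residues x real CDR-beta positions.
#' @export
peptide_cdrb_scores <- function(maps, enc, record = 1L,
                                aggregation = "mean") {
  P <- maps$pep  # (B, Lp, LA + LB, H)
  Lp <- dim(P)[2]; H <- dim(P)[4]
  LA <- ncol(enc$chainA); LB <- ncol(enc$chainB)
  if (identical(aggregation, "mean")) {
    m <- mean_head_map(P, record)
  } else {
    h <- as.integer(aggregation)
    if (is.na(h) || h < 1L || h > H) {
      stop("aggregation must be 'mean' or a head index in 1..", H,
           call. = FALSE)
    }
    m <- matrix(P[record, , , h], Lp, LA + LB)
  }
  beta_block <- m[, LA + seq_len(LB), drop = FALSE]
  pep_real <- which(enc$pep[record, ] > 0L)
  beta_real <- which(enc$chainB[record, ] > 0L)
  beta_block[pep_real, beta_real, drop = FALSE]
}
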