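# Convolutional model: seven parallel branches (peptide + six CDRs),
# each a kernel-2 1D convolution over the one-hot sequence, kernel-2
# max-pooling, and a fully connected projection; branch outputs are
# concatenated and passed through a three-layer sigmoid head.
#
# The convolution over a one-hot input is computed in its
# embedding-lookup form: with kernel width 2, the pre-activation at
# position t is Wl[residue_t, ] + Wr[residue_{t+1}, ] + b, so a 21-row
# lookup table (row 1 = pad, all zeros) replaces the explicit one-hot
# matrix product. The two formulations are algebraically identical.

#' CNN model configuration
#'
#' @param conv_channels Convolution output channels per branch.
#' @param kernel_size Convolution kernel width (fixed at 2 by the
#'   architecture; overriding is possible but changes the model family).
#' @param pool_size Max-pooling width (fixed at 2; odd remainders are
#'   dropped, i.e. floor division).
#' @param branch_fc_dim Output width of each branch's fully connected
#'   layer (identical across branches regardless of slot length).
#' @param head_dims Widths of the three head layers; last must be 1.
#' @param dropout Dropout rate on the head's hidden layers during
#'   training.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(conv_channels = 32L, kernel_size = 2L,
                       pool_size = 2L, branch_fc_dim = 32L,
                       head_dims = c(64L, 16L, 1L), dropout = 0.3) {
  stopifnot(kernel_size == 2L, pool_size == 2L,
            utils::tail(head_dims, 1L) == 1L, length(head_dims) == 3L,
            dropout >= 0, dropout < 1)
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel_size = 2L, pool_size = 2L,
                 branch_fc_dim = as.integer(branch_fc_dim),
                 head_dims = as.integer(head_dims),
                 dropout = dropout),
            class = "cnn_config")
}

# shape arithmetic: post-conv length L - 1, post-pool floor((L - 1) / 2)
cnn_shapes <- function(L, cfg) {
  conv_len <- L - cfg$kernel_size + 1L
  pool_len <- conv_len %/% cfg$pool_size
  list(conv_len = conv_len, pool_len = pool_len,
       flat = pool_len * cfg$conv_channels)
}

cnn_init <- function(spec, cfg, seed) {
  withr::with_seed(seed, {
    C <- cfg$conv_channels
    branches <- lapply(seq_slots(), function(s) {
      L <- spec$max_len[[s]]
      sh <- cnn_shapes(L, cfg)
      if (sh$pool_len < 1L) {
        stop("slot ", s, " of length ", L, " too short for conv+pool",
             call. = FALSE)
      }
      list(Wl = glorot(20L, C), Wr = glorot(20L, C), bconv = numeric(C),
           Wfc = glorot(sh$flat, cfg$branch_fc_dim),
           bfc = numeric(cfg$branch_fc_dim))
    })
    names(branches) <- seq_slots()
    h <- cfg$head_dims
    concat_dim <- 7L * cfg$branch_fc_dim
    head <- list(W1 = glorot(concat_dim, h[1]), b1 = numeric(h[1]),
                 W2 = glorot(h[1], h[2]), b2 = numeric(h[2]),
                 W3 = glorot(h[2], 1L), b3 = numeric(1L))
    list(branches = branches, head = head)
  })
}

# One branch forward. A: B x L integer index matrix (0 = pad).
cnn_branch_forward <- function(par, A, cfg) {
  B <- nrow(A); L <- ncol(A)
  sh <- cnn_shapes(L, cfg)
  C <- cfg$conv_channels
  El <- rbind(0, par$Wl)  # row 1: pad contributes nothing
  Er <- rbind(0, par$Wr)
  H <- vector("list", sh$conv_len)
  for (t in seq_len(sh$conv_len)) {
    pre <- El[A[, t] + 1L, , drop = FALSE] +
      Er[A[, t + 1L] + 1L, , drop = FALSE]
    H[[t]] <- relu(sweep(pre, 2L, par$bconv, `+`))
  }
  Pool <- vector("list", sh$pool_len)
  left_max <- logical(0)
  which_left <- vector("list", sh$pool_len)
  for (u in seq_len(sh$pool_len)) {
    a <- H[[2L * u - 1L]]; b <- H[[2L * u]]
    Pool[[u]] <- pmax(a, b)
    which_left[[u]] <- a >= b
  }
  Fmat <- do.call(cbind, Pool)  # B x (pool_len * C)
  Zpre <- sweep(Fmat %*% par$Wfc, 2L, par$bfc, `+`)
  Z <- relu(Zpre)
  list(out = Z, cache = list(A = A, H = H, which_left = which_left,
                             Fmat = Fmat, Zpre = Zpre, sh = sh))
}

cnn_branch_backward <- function(par, cache, dZ, cfg) {
  sh <- cache$sh; C <- cfg$conv_channels
  dZpre <- dZ * (cache$Zpre > 0)
  gWfc <- crossprod(cache$Fmat, dZpre)
  gbfc <- colSums(dZpre)
  dF <- dZpre %*% t(par$Wfc)
  gWl <- matrix(0, 20L, C); gWr <- matrix(0, 20L, C)
  gbconv <- numeric(C)
  A <- cache$A
  for (u in seq_len(sh$pool_len)) {
    dPu <- dF[, (u - 1L) * C + seq_len(C), drop = FALSE]
    wl <- cache$which_left[[u]]
    for (side in 1:2) {
      t <- 2L * u - 2L + side
      mask <- if (side == 1L) wl else !wl
      dH <- dPu * mask * (cache$H[[t]] > 0)
      gbconv <- gbconv + colSums(dH)
      # scatter-add into the lookup rows by residue index
      gl <- rowsum(dH, group = A[, t])
      gr <- rowsum(dH, group = A[, t + 1L])
      add_rows <- function(g, acc) {
        idx <- as.integer(rownames(g))
        keep <- idx > 0L
        acc[idx[keep], ] <- acc[idx[keep], ] + g[keep, , drop = FALSE]
        acc
      }
      gWl <- add_rows(gl, gWl)
      gWr <- add_rows(gr, gWr)
    }
  }
  list(Wl = gWl, Wr = gWr, bconv = gbconv, Wfc = gWfc, bfc = gbfc)
}

# Full forward. enc: encode_dataset() result; training toggles dropout
# (masks drawn from the active RNG stream).
cnn_forward <- function(params, enc, cfg, training = FALSE) {
  slots <- seq_slots()
  branch <- lapply(slots, function(s) {
    cnn_branch_forward(params$branches[[s]], enc$cnn[[s]], cfg)
  })
  names(branch) <- slots
  Xc <- do.call(cbind, lapply(branch, `[[`, "out"))
  hp <- params$head
  drop1 <- drop2 <- NULL
  Z1pre <- sweep(Xc %*% hp$W1, 2L, hp$b1, `+`)
  Z1 <- relu(Z1pre)
  if (training && cfg$dropout > 0) {
    drop1 <- dropout_mask(nrow(Z1), ncol(Z1), cfg$dropout)
    Z1 <- Z1 * drop1
  }
  Z2pre <- sweep(Z1 %*% hp$W2, 2L, hp$b2, `+`)
  Z2 <- relu(Z2pre)
  if (training && cfg$dropout > 0) {
    drop2 <- dropout_mask(nrow(Z2), ncol(Z2), cfg$dropout)
    Z2 <- Z2 * drop2
  }
  logit <- drop(sweep(Z2 %*% hp$W3, 2L, hp$b3, `+`))
  p <- sigmoid(logit)
  list(prob = p,
       cache = list(branch = branch, Xc = Xc, Z1pre = Z1pre, Z1 = Z1,
                    Z2pre = Z2pre, Z2 = Z2, drop1 = drop1, drop2 = drop2))
}

# dlogit: dLoss/dlogit per example (for BCE with sigmoid: (p - y) / B)
cnn_backward <- function(params, cache, dlogit, cfg) {
  hp <- params$head
  dlogit <- matrix(dlogit, ncol = 1L)
  gW3 <- crossprod(cache$Z2, dlogit)
  gb3 <- sum(dlogit)
  dZ2 <- dlogit %*% t(hp$W3)
  if (!is.null(cache$drop2)) dZ2 <- dZ2 * cache$drop2
  dZ2 <- dZ2 * (cache$Z2pre > 0)
  gW2 <- crossprod(cache$Z1, dZ2)
  gb2 <- colSums(dZ2)
  dZ1 <- dZ2 %*% t(hp$W2)
  if (!is.null(cache$drop1)) dZ1 <- dZ1 * cache$drop1
  dZ1 <- dZ1 * (cache$Z1pre > 0)
  gW1 <- crossprod(cache$Xc, dZ1)
  gb1 <- colSums(dZ1)
  dXc <- dZ1 %*% t(hp$W1)
  Fd <- cfg$branch_fc_dim
  slots <- seq_slots()
  gbranch <- lapply(seq_along(slots), function(i) {
    dZ <- dXc[, (i - 1L) * Fd + seq_len(Fd), drop = FALSE]
    cnn_branch_backward(params$branches[[slots[i]]],
                        cache$branch[[slots[i]]]$cache, dZ, cfg)
  })
  names(gbranch) <- slots
  list(branches = gbranch,
       head = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                   W3 = gW3, b3 = gb3))
}
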