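# Minimal neural-network primitives: initialization, Adam, and the
# batched multi-head attention forward/backward used by the attention
# model. Everything is plain double-precision matrix algebra, vectorized
# over the batch dimension; explicit backprop, no autodiff.

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

relu <- function(x) (x > 0) * x

sigmoid <- function(x) 1 / (1 + exp(-x))

# binary cross-entropy, clamped for numerical safety
bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# --- Adam over an arbitrarily nested list of numeric arrays ------------

adam_init <- function(params) {
  zeros <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# elementwise sum of two parameter lists (gradient accumulation)
grad_add <- function(a, b) {
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- grad_add(a[[k]], b[[k]])
    a
  } else a + b
}

n_params <- function(params) {
  sum(rapply(params, length, how = "unlist"))
}

# fast row-broadcast bias addition (cheaper than sweep)
add_bias <- function(M, b) {
  M + rep(b, each = nrow(M))
}

# inverted dropout mask (drawn from the active RNG stream)
dropout_mask <- function(n_row, n_col, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(n_row * n_col, 1L, 1 - rate) / (1 - rate),
         n_row, n_col)
}

# --- batched multi-head attention --------------------------------------
#
# Representations are (B, L, d) arrays; matrix(X, B*L, d) flattens the
# batch/position axes (column-major, positions vary slower), and
# array(M, c(B, L, d)) undoes it. Attention probabilities are stored as
# (B, Lq, Lk, H) arrays. Loops run over key positions and feature
# indices; every inner operation is vectorized over (batch x query).

# projection weights; bias-free, as is standard for attention blocks
mha_params <- function(d) {
  list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
       Wo = glorot(d, d))
}

# Xq: (B, Lq, d) query-side input; Xk: (B, Lk, d) key/value-side input;
# mask_k: B x Lk (1 = real). Returns output (B, Lq, d) and a cache for
# the backward pass (including the attention probabilities P).
# The batched contractions run in compiled code (src/).
mha_forward <- function(par, Xq, Xk, mask_k, n_heads) {
  dims_q <- dim(Xq); B <- dims_q[1]; Lq <- dims_q[2]; d <- dims_q[3]
  Lk <- dim(Xk)[2]
  dk <- d %/% n_heads
  stopifnot(dk * n_heads == d)
  scale <- 1 / sqrt(dk)
  Xkm0 <- matrix(Xk, B * Lk, d)
  Qm <- matrix(Xq, B * Lq, d) %*% par$Wq
  Km <- Xkm0 %*% par$Wk
  Vm <- Xkm0 %*% par$Wv
  Q <- array(Qm, c(B, Lq, d))
  K <- array(Km, c(B, Lk, d))
  V <- array(Vm, c(B, Lk, d))
  S <- .bat_scores(Q, K, n_heads, scale)
  P <- .masked_softmax(S, mask_k)
  O <- .bat_attend(P, V)
  Om <- matrix(O, B * Lq, d)
  Ym <- Om %*% par$Wo
  list(out = array(Ym, c(B, Lq, d)),
       cache = list(Xq = Xq, Xk = Xk, Q = Q, K = K, V = V, P = P, Om = Om,
                    mask_k = mask_k, n_heads = n_heads, scale = scale))
}

# dY: (B, Lq, d) gradient on the layer output. Returns gradients on the
# parameters and on both inputs.
mha_backward <- function(par, cache, dY) {
  Q <- cache$Q; K <- cache$K; V <- cache$V; P <- cache$P
  B <- dim(Q)[1]; Lq <- dim(Q)[2]; d <- dim(Q)[3]; Lk <- dim(K)[2]
  n_heads <- cache$n_heads
  scale <- cache$scale
  dYm <- matrix(dY, B * Lq, d)
  dWo <- crossprod(cache$Om, dYm)
  dOm <- dYm %*% t(par$Wo)
  dO <- array(dOm, c(B, Lq, d))
  # value contraction: dP pairs dO with V; dV is the transposed form
  dP <- .bat_scores(dO, V, n_heads, 1)
  dV <- .bat_attend_t(P, dO)
  dS <- .softmax_backward(P, dP)
  # through the scores
  dQ <- .bat_attend(dS, K) * scale
  dK <- .bat_attend_t(dS, Q) * scale
  dim(dK) <- c(B, Lk, d)
  Xqm <- matrix(cache$Xq, B * Lq, d)
  Xkm <- matrix(cache$Xk, B * Lk, d)
  dQm <- matrix(dQ, B * Lq, d)
  dKm <- matrix(dK, B * Lk, d)
  dVm <- matrix(dV, B * Lk, d)
  grads <- list(Wq = crossprod(Xqm, dQm), Wk = crossprod(Xkm, dKm),
                Wv = crossprod(Xkm, dVm), Wo = dWo)
  dXq <- array(dQm %*% t(par$Wq), c(B, Lq, d))
  dXk_m <- dKm %*% t(par$Wk) + dVm %*% t(par$Wv)
  dXk <- array(dXk_m, c(B, Lk, d))
  list(grads = grads, dXq = dXq, dXk = dXk)
}

# head-averaged attention map of one record from a (B, Lq, Lk, H) array
mean_head_map <- function(P, b) {
  Lq <- dim(P)[2]; Lk <- dim(P)[3]; H <- dim(P)[4]
  m <- matrix(0, Lq, Lk)
  for (h in seq_len(H)) m <- m + matrix(P[b, , , h], Lq, Lk)
  m / H
}
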