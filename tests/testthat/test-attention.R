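# Architecture contracts of the reciprocal-attention model.

att_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rep_ <- small_repertoire()
      ds <- rep_$positives[1:12, ]
      spec <- fit_padding_spec(ds)
      cfg <- attention_config(embed_dim = 16, n_heads = 2, dropout = 0)
      par <- tcrpred:::att_init(spec, cfg, seed = 5)
      enc <- tcrpred:::encode_dataset(ds, spec)
      cache <<- list(ds = ds, spec = spec, cfg = cfg, par = par, enc = enc)
    }
    cache
  }
})

test_that("attention rows sum to one with zero mass on pad keys", {
  fx <- att_fixture()
  f <- tcrpred:::att_forward(fx$par, fx$enc, fx$cfg)
  for (nm in c("pep", "A", "B")) {
    P <- f$maps[[nm]]
    B <- dim(P)[1]; Lq <- dim(P)[2]; Lk <- dim(P)[3]; H <- dim(P)[4]
    mask_k <- if (nm == "pep") {
      cbind(fx$enc$chainA > 0, fx$enc$chainB > 0)
    } else {
      fx$enc$pep > 0
    }
    sums <- apply(P, c(1, 2, 4), sum)
    expect_equal(as.vector(sums), rep(1, B * Lq * H), tolerance = 1e-6)
    for (j in seq_len(Lk)) {
      pad_rows <- which(!mask_k[, j])
      if (length(pad_rows)) {
        expect_equal(max(abs(P[pad_rows, , j, ])), 0)
      }
    }
  }
})

test_that("a single real key receives all attention weight", {
  # length-1 key/value sequence: every query row attends with weight 1
  withr::with_seed(31, {
    par <- tcrpred:::mha_params(8)
    Xq <- array(rnorm(2 * 3 * 8), c(2, 3, 8))
    Xk <- array(rnorm(2 * 1 * 8), c(2, 1, 8))
  })
  f <- tcrpred:::mha_forward(par, Xq, Xk, matrix(1, 2, 1), n_heads = 2)
  expect_equal(as.vector(f$cache$P), rep(1, 2 * 3 * 2))
  # self-attention of a length-1 sequence: weight matrix [[1]]
  f2 <- tcrpred:::mha_forward(par, Xk, Xk, matrix(1, 2, 1), n_heads = 2)
  expect_equal(as.vector(f2$cache$P), rep(1, 2 * 2))  # 2 records x 2 heads
})

test_that("zeroing values zeroes the output but not the attention map", {
  withr::with_seed(37, {
    par <- tcrpred:::mha_params(8)
    Xq <- array(rnorm(2 * 3 * 8), c(2, 3, 8))
    Xk <- array(rnorm(2 * 4 * 8), c(2, 4, 8))
  })
  mask <- matrix(1, 2, 4)
  f <- tcrpred:::mha_forward(par, Xq, Xk, mask, n_heads = 2)
  par0 <- par; par0$Wv <- par$Wv * 0
  f0 <- tcrpred:::mha_forward(par0, Xq, Xk, mask, n_heads = 2)
  expect_equal(max(abs(f0$out)), 0)
  expect_equal(f0$cache$P, f$cache$P)
})

test_that("perturbing pad embeddings leaves real outputs unchanged", {
  fx <- att_fixture()
  f <- tcrpred:::att_forward(fx$par, fx$enc, fx$cfg)
  # hand the forward pass an encoding whose pads got a different token
  # interpretation by shifting the pad row of the embedding table: pads
  # are index 0 and masked, so nothing downstream may change
  par2 <- fx$par
  # perturb positional embeddings at pad-only positions of chain B
  pad_cols <- which(colSums(fx$enc$chainB > 0) == 0)
  if (length(pad_cols)) {
    par2$pos$B[pad_cols, ] <- par2$pos$B[pad_cols, ] + 5
  }
  f2 <- tcrpred:::att_forward(par2, fx$enc, fx$cfg)
  expect_equal(f2$prob, f$prob, tolerance = 1e-12)
})

test_that("reciprocal wiring responds to its stated inputs only", {
  fx <- att_fixture()
  f <- tcrpred:::att_forward(fx$par, fx$enc, fx$cfg)
  # perturb the alpha-chain self-attention output by changing alpha
  # tokens: the peptide-query map must change (alpha is among its keys),
  # and the beta-query map must not (its keys are the peptide only)
  enc2 <- fx$enc
  ia <- which(enc2$chainA[1, ] > 0)
  enc2$chainA[1, ia[1]] <- (enc2$chainA[1, ia[1]] %% 20L) + 1L
  f2 <- tcrpred:::att_forward(fx$par, enc2, fx$cfg)
  expect_gt(max(abs(f2$maps$pep[1, , , ] - f$maps$pep[1, , , ])), 1e-8)
  expect_equal(f2$maps$B[1, , , ], f$maps$B[1, , , ], tolerance = 1e-12)
  # perturbing the peptide changes the alpha- and beta-query maps
  enc3 <- fx$enc
  ip <- which(enc3$pep[1, ] > 0)
  enc3$pep[1, ip[1]] <- (enc3$pep[1, ip[1]] %% 20L) + 1L
  f3 <- tcrpred:::att_forward(fx$par, enc3, fx$cfg)
  expect_gt(max(abs(f3$maps$A[1, , , ] - f$maps$A[1, , , ])), 1e-8)
  expect_gt(max(abs(f3$maps$B[1, , , ] - f$maps$B[1, , , ])), 1e-8)
  # other records are untouched (batch independence)
  expect_equal(f3$maps$pep[2, , , ], f$maps$pep[2, , , ],
               tolerance = 1e-12)
})

test_that("forward outputs are probabilities, deterministic in eval mode", {
  fx <- att_fixture()
  f1 <- tcrpred:::att_forward(fx$par, fx$enc, fx$cfg)
  f2 <- tcrpred:::att_forward(fx$par, fx$enc, fx$cfg)
  expect_true(all(f1$prob > 0 & f1$prob < 1))
  expect_identical(f1$prob, f2$prob)
  # all-pad input is rejected
  enc_bad <- fx$enc
  enc_bad$pep[1, ] <- 0L
  expect_error(tcrpred:::att_forward(fx$par, enc_bad, fx$cfg), "all-pad")
})

test_that("peptide-to-CDRb score extraction averages heads and drops pads", {
  fx <- att_fixture()
  f <- tcrpred:::att_forward(fx$par, fx$enc, fx$cfg)
  sc <- peptide_cdrb_scores(f$maps, fx$enc, record = 3)
  np <- sum(fx$enc$pep[3, ] > 0)
  nb <- sum(fx$enc$chainB[3, ] > 0)
  expect_equal(dim(sc), c(np, nb))
  # brute-force per-cell head averaging on the beta block
  P <- f$maps$pep
  LA <- ncol(fx$enc$chainA)
  pep_real <- which(fx$enc$pep[3, ] > 0)
  beta_real <- which(fx$enc$chainB[3, ] > 0)
  H <- dim(P)[4]
  for (i in seq_len(np)) for (j in seq_len(min(nb, 4))) {
    manual <- mean(vapply(seq_len(H), function(h) {
      P[3, pep_real[i], LA + beta_real[j], h]
    }, numeric(1)))
    expect_equal(sc[i, j], manual, tolerance = 1e-12)
  }
  # single-head extraction is the identity on the beta block
  sc1 <- peptide_cdrb_scores(f$maps, fx$enc, record = 3, aggregation = 1)
  expect_equal(sc1[1, 1], P[3, pep_real[1], LA + beta_real[1], 1])
  expect_error(peptide_cdrb_scores(f$maps, fx$enc, 3, aggregation = 99),
               "head index")
})

test_that("one-batch overfit: attention loss decreases over 50 steps", {
  rep_ <- small_repertoire()
  ds <- rep_$positives[1:8, ]
  ds$binder <- rep(c(1L, 0L), 4)
  spec <- fit_padding_spec(ds)
  cfg <- attention_config(embed_dim = 16, n_heads = 2, dropout = 0)
  enc <- tcrpred:::encode_dataset(ds, spec)
  y <- as.numeric(ds$binder)
  par <- tcrpred:::att_init(spec, cfg, seed = 3)
  opt <- tcrpred:::adam_init(par)
  losses <- numeric(50)
  for (step in 1:50) {
    f <- tcrpred:::att_forward(par, enc, cfg)
    losses[step] <- tcrpred:::bce_loss(f$prob, y)
    g <- tcrpred:::att_backward(par, f$cache, (f$prob - y) / 8, cfg)
    st <- tcrpred:::adam_step(par, g, opt, lr = 5e-3)
    par <- st$params; opt <- st$state
  }
  expect_lt(losses[50], losses[1] / 2)
})

test_that("ensemble prediction is the arithmetic mean with its identities", {
  expect_equal(ensemble_predict(0.4, 0.6), 0.5)
  expect_equal(ensemble_predict(0.7, 0.7), 0.7)
  withr::with_seed(5, {
    a <- runif(20); b <- runif(20)
  })
  e <- ensemble_predict(a, b)
  expect_equal(e, ensemble_predict(b, a))
  expect_true(all(e >= pmin(a, b) & e <= pmax(a, b)))
  expect_error(ensemble_predict(1.2, 0.5))
})
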