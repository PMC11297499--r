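# Training with validation-ROC-AUC epoch selection, prediction, and the
# two-model ensemble.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (defaults: 1e-3 for the CNN,
#'   5e-4 for the attention model; see [train_model()]).
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum epochs (>= 1).
#' @param patience Epochs without validation ROC-AUC improvement before
#'   stopping (>= 1, <= `max_epochs`).
#' @param seed Integer seed controlling initialization, batch order, and
#'   dropout; equal seeds give identical runs.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = NULL, batch_size = 128L,
                         max_epochs = 200L, patience = 20L, seed = 1L) {
  stopifnot(max_epochs >= 1L, patience >= 1L, patience <= max_epochs,
            batch_size >= 1L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a binding-prediction model
#'
#' Trains either the convolutional or the reciprocal-attention model with
#' binary cross-entropy and Adam. After every epoch the validation
#' ROC-AUC is recorded; the returned model carries the weights of the
#' best-validation epoch (the epoch-selection criterion). Training stops
#' early after `patience` epochs without improvement. The run is fully
#' seeded: initialization, batch shuffling, and dropout all derive from
#' `config$seed`.
#'
#' @param train_data,val_data Labeled dataset tibbles; they must be
#'   disjoint partitions (use [audit_leakage()]), and the validation set
#'   must contain both classes or ROC-AUC is undefined and training
#'   refuses to start.
#' @param model `"cnn"` or `"attention"`.
#' @param config A [train_config()].
#' @param model_config A [cnn_config()] or [attention_config()]; default
#'   per model type.
#' @param spec Padding spec; defaults to fitting on `train_data` (mode
#'   `pad_then_concat`). Pass a `concat_then_pad` spec for models meant
#'   for attention-map interpretation.
#' @param verbose Print one line per epoch.
#' @return A `tcr_model` object: parameters at the best epoch, configs,
#'   the padding spec, and the per-epoch `history` tibble.
#' @export
train_model <- function(train_data, val_data,
                        model = c("cnn", "attention"),
                        config = train_config(),
                        model_config = NULL, spec = NULL,
                        verbose = FALSE) {
  model <- match.arg(model)
  if (length(unique(val_data$binder)) < 2L) {
    stop("validation set is single-class; ROC-AUC undefined", call. = FALSE)
  }
  if (is.null(spec)) spec <- fit_padding_spec(train_data)
  if (is.null(model_config)) {
    model_config <- if (model == "cnn") cnn_config() else attention_config()
  }
  lr <- config$learning_rate %||%
    (if (model == "cnn") 1e-3 else 5e-4)
  enc_train <- encode_dataset(train_data, spec)
  enc_val <- encode_dataset(val_data, spec)
  y <- as.numeric(train_data$binder)
  y_val <- as.numeric(val_data$binder)
  n <- nrow(train_data)
  fwd <- if (model == "cnn") cnn_forward else att_forward
  bwd <- if (model == "cnn") cnn_backward else att_backward
  params <- if (model == "cnn") {
    cnn_init(spec, model_config, config$seed)
  } else {
    att_init(spec, model_config, config$seed)
  }
  opt <- adam_init(params)
  history <- vector("list", config$max_epochs)
  best <- list(auc = -Inf, params = params, epoch = 0L)
  withr::with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      epoch_loss <- 0
      for (idx in batches) {
        enc_b <- subset_encoding(enc_train, idx)
        f <- fwd(params, enc_b, model_config, training = TRUE)
        yb <- y[idx]
        epoch_loss <- epoch_loss + bce_loss(f$prob, yb) * length(idx)
        dlogit <- (f$prob - yb) / length(idx)
        g <- bwd(params, f$cache, dlogit, model_config)
        st <- adam_step(params, g, opt, lr = lr)
        params <- st$params
        opt <- st$state
      }
      val_scores <- predict_scores(params, enc_val, model, model_config)
      val_auc <- roc_auc(y_val, val_scores)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = epoch_loss / n, val_roc_auc = val_auc)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val ROC-AUC %.4f",
                        epoch, epoch_loss / n, val_auc))
      }
      if (val_auc > best$auc) {
        best <- list(auc = val_auc, params = params, epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) {
        break
      }
    }
  })
  history <- dplyr::bind_rows(history)
  history$best <- history$epoch == best$epoch
  structure(
    list(model = model, params = best$params, model_config = model_config,
         spec = spec, train_config = config, history = history,
         best_epoch = best$epoch, best_val_roc_auc = best$auc,
         alphabet = aa_alphabet()),
    class = "tcr_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

subset_encoding <- function(enc, idx) {
  list(cnn = lapply(enc$cnn, function(m) m[idx, , drop = FALSE]),
       pep = enc$pep[idx, , drop = FALSE],
       chainA = enc$chainA[idx, , drop = FALSE],
       chainB = enc$chainB[idx, , drop = FALSE])
}

# evaluation-mode scores, batched to bound memory
predict_scores <- function(params, enc, model, model_config,
                           batch_size = 1024L) {
  n <- nrow(enc$pep)
  fwd <- if (model == "cnn") cnn_forward else att_forward
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    f <- fwd(params, subset_encoding(enc, idx), model_config,
             training = FALSE)
    out[idx] <- f$prob
  }
  out
}

#' @export
print.tcr_model <- function(x, ...) {
  cat("<tcr_model>", x$model, "-", n_params(x$params), "parameters\n")
  cat("best epoch", x$best_epoch, "of", nrow(x$history),
      sprintf("(val ROC-AUC %.4f)\n", x$best_val_roc_auc))
  invisible(x)
}

#' Predict binding probabilities
#'
#' @param object A fitted `tcr_model`.
#' @param data Dataset tibble (labels not required).
#' @param type `"score"` returns the input tibble with a `score` column;
#'   `"maps"` additionally returns attention score matrices (attention
#'   models only).
#' @param ... Unused.
#' @return The tibble with a `score` column, or for `type = "maps"` a
#'   list with `scores` and per-record `maps`.
#' @export
predict.tcr_model <- function(object, data, type = c("score", "maps"),
                              ...) {
  type <- match.arg(type)
  enc <- encode_dataset(data, object$spec)
  if (type == "score") {
    data$score <- predict_scores(object$params, enc, object$model,
                                 object$model_config)
    return(data)
  }
  if (object$model != "attention") {
    stop("attention maps are only available for attention models",
         call. = FALSE)
  }
  f <- att_forward(object$params, enc, object$model_config,
                   training = FALSE)
  maps <- lapply(seq_len(nrow(data)), function(b) {
    peptide_cdrb_scores(f$maps, enc, record = b)
  })
  data$score <- f$prob
  list(scores = data, maps = maps)
}

#' Ensemble prediction
#'
#' The ensemble score is the arithmetic mean of the two component model
#' probabilities.
#'
#' @param p_cnn,p_att Probability vectors from the two models.
#' @return Mean probability vector.
#' @export
#' @examples
#' ensemble_predict(0.4, 0.6)  # 0.5
ensemble_predict <- function(p_cnn, p_att) {
  stopifnot(length(p_cnn) == length(p_att),
            all(p_cnn >= 0 & p_cnn <= 1), all(p_att >= 0 & p_att <= 1))
  (p_cnn + p_att) / 2
}
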