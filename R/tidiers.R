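# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model's training history
#'
#' @param x A `tcr_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_roc_auc`, `best`.
#' @export
tidy.tcr_model <- function(x, ...) {
  x$history
}

#' One-row model summary
#'
#' @param x A `tcr_model`.
#' @param ... Unused.
#' @return Tibble with model type, parameter count, epochs run, best
#'   epoch, and best validation ROC-AUC.
#' @export
glance.tcr_model <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_parameters = n_params(x$params),
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_roc_auc = x$best_val_roc_auc
  )
}

#' Tidy a structure comparison
#'
#' @param x A `structure_comparison`.
#' @param ... Unused.
#' @return The per-complex tibble of close/far mean attention scores.
#' @export
tidy.structure_comparison <- function(x, ...) {
  x$per_complex
}

#' One-row structure-comparison summary
#'
#' @param x A `structure_comparison`.
#' @param ... Unused.
#' @return Tibble with group means, SDs, the t statistic, and p-value.
#' @export
glance.structure_comparison <- function(x, ...) {
  g <- x$group_stats
  tibble::tibble(
    mean_close = g$mean[1], sd_close = g$sd[1],
    mean_far = g$mean[2], sd_far = g$sd[2],
    n_complexes = g$n[1],
    t_statistic = x$test$statistic, df = x$test$df,
    p_value = x$test$p_value, variant = x$test$variant
  )
}

#' Plot a training history
#'
#' Validation ROC-AUC by epoch with the selected epoch marked.
#'
#' @param object A `tcr_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tcr_model <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$val_roc_auc)) +
    ggplot2::geom_point(data = h[h$best, , drop = FALSE],
                        ggplot2::aes(y = .data$val_roc_auc),
                        shape = 21, size = 3) +
    ggplot2::labs(x = "epoch", y = "validation ROC-AUC",
                  title = paste("training history:", object$model)) +
    ggplot2::theme_minimal()
}

#' Plot a distance map
#'
#' Heatmap of peptide x CDR-beta residue distances.
#'
#' @param object A `distance_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.distance_map <- function(object, ...) {
  df <- tidyr::expand_grid(pep = seq_len(nrow(object$d)),
                           cdrb = seq_len(ncol(object$d)))
  df$distance <- as.vector(t(object$d))[
    (df$pep - 1L) * ncol(object$d) + df$cdrb]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cdrb, y = .data$pep,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "distance (Å)",
                                  direction = -1) +
    ggplot2::labs(x = "CDR-beta position", y = "peptide position",
                  title = object$complex_id) +
    ggplot2::theme_minimal()
}

#' Plot a structure comparison
#'
#' Paired per-complex close/far mean attention scores.
#'
#' @param object A `structure_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.structure_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_complex,
                              c("mean_close", "mean_far"),
                              names_to = "group", values_to = "score")
  long$group <- sub("mean_", "", long$group)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_line(ggplot2::aes(group = .data$complex_id),
                       alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "mean attention score",
                  subtitle = sprintf("%s t-test p = %.3g",
                                     object$test$variant,
                                     object$test$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot per-peptide ROC-AUC against peptide frequency
#'
#' @param per_peptide Tibble from [per_peptide_auc()].
#' @return A ggplot.
#' @export
plot_per_peptide_auc <- function(per_peptide) {
  pp <- per_peptide[per_peptide$defined, , drop = FALSE]
  ggplot2::ggplot(pp, ggplot2::aes(x = .data$n_pos, y = .data$roc_auc)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "positive samples per peptide (log scale)",
                  y = "per-peptide ROC-AUC") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
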