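#' Plot a ROC curve
#'
#' @param object A `phos_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.phos_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate (1 - SP)",
                  y = "True-positive rate (SE)",
                  title = sprintf("ROC curve (AUC = %.4f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot the training history of a CNN
#'
#' @param model A trained `phoscnn_model`.
#' @return A ggplot of loss and training accuracy per epoch.
#' @export
plot_training_history <- function(model) {
  h <- tidyr::pivot_longer(model$history, c("loss", "accuracy"),
                           names_to = "metric")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' Plot a position-specific enrichment profile
#'
#' Heat map of the positive-minus-negative frequency difference per
#' (offset, residue) cell; significant cells are outlined.
#'
#' @param object An `enrichment_profile` from [position_enrichment()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$residue,
                                   fill = .data$difference)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$significant, ], fill = NA,
                       colour = "black", linewidth = 0.4) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = "Offset from phosphosite", y = "Residue",
                  fill = "freq diff",
                  title = "Position-specific residue enrichment") +
    ggplot2::theme_minimal()
}

#' Plot the K-selection criterion curve
#'
#' @param object A `cluster_result` from [kmeans_windows()].
#' @param ... Unused.
#' @return A ggplot with the selected K marked.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_result <- function(object, ...) {
  ggplot2::ggplot(object$criterion,
                  ggplot2::aes(x = .data$K, y = .data$mean_within)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$K, linetype = "dashed",
                        colour = "#b2182b") +
    ggplot2::labs(x = "K", y = "Mean within-cluster distance",
                  title = sprintf("K-means criterion (selected K = %d)",
                                  object$K)) +
    ggplot2::theme_minimal()
}

#' Plot the peptide-length optimization curve
#'
#' @param length_table Result of [run_length_optimization()].
#' @param metric Column to plot (default `"acc"`).
#' @return A ggplot.
#' @export
plot_length_curve <- function(length_table, metric = "acc") {
  ggplot2::ggplot(length_table,
                  ggplot2::aes(x = .data$window_length,
                               y = .data[[metric]])) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Window length (2n + 1)", y = toupper(metric),
                  title = "Peptide-length optimization") +
    ggplot2::theme_minimal()
}

#' Bar plot of the method comparison
#'
#' @param object A `phos_comparison` from [compare_methods()].
#' @param metric `"acc"`, `"mcc"` or `"auc"` (default `"acc"`).
#' @param ... Unused.
#' @return A ggplot with mean +/- sd error bars.
#' @exportS3Method ggplot2::autoplot
autoplot.phos_comparison <- function(object, metric = "acc", ...) {
  mcol <- paste0(metric, "_mean"); scol <- paste0(metric, "_sd")
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$method,
                                                      .data[[mcol]]),
                                   y = .data[[mcol]])) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                        ymax = .data[[mcol]] + .data[[scol]]),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = toupper(metric),
                  title = "Method comparison") +
    ggplot2::theme_minimal()
}
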