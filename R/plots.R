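#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scintigraphic image
#'
#' Renders a count image (view or composite) as a ggplot raster with a
#' square-root intensity stretch, which keeps faint skeletal structure
#' visible next to hot lesions and confounders.
#'
#' @param image Numeric matrix (height x width).
#' @param title Optional title.
#' @return A ggplot object.
#' @export
plot_scinti_image <- function(image, title = NULL) {
  df <- tidyr::expand_grid(row = seq_len(nrow(image)), col = seq_len(ncol(image)))
  df$value <- as.numeric(image[cbind(df$row, df$col)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = sqrt(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = expression(sqrt(counts))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.composite_image <- function(object, ...) {
  plot_scinti_image(object$pixels,
                    title = sprintf("%s (%s)", object$study_id, object$label))
}

#' @export
autoplot.scinti_roc <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (macro AUC %.3f, micro AUC %.3f)",
                      object$macro_auc, object$micro_auc)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scinti_model <- function(object, ...) {
  h <- tidy(object)
  if (nrow(h) == 0) abort("Model has no training history to plot")
  long <- tidyr::pivot_longer(h, c("loss", "accuracy"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL, title = "Training history") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scinti_confusion <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::labs(x = "Predicted", y = "True", title = "Confusion matrix") +
    ggplot2::theme_minimal()
}
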