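#' Plot a ROC curve
#'
#' @param object A `qsar_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qsar_roc
#' @export
autoplot.qsar_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$FPR, y = .data$TPR)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate (1 - SP)",
      y = "True positive rate (SE)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a GA fitness trajectory
#'
#' Best-ever and generation-mean cross-validated fitness per generation.
#'
#' @param object A `ga_result` from [ga_search()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$fitness_history,
                              cols = c("best", "mean"),
                              names_to = "series", values_to = "fitness")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation,
                                     y = .data$fitness,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Generation", y = "CV fitness", colour = NULL,
                  title = "Genetic-algorithm descriptor selection") +
    ggplot2::theme_minimal()
}

#' Plot the output layer of a counter-propagation network
#'
#' Tile map of the output weight on the Kohonen grid — for a classifier
#' this is the activity landscape the winning-neuron lookup reads from.
#'
#' @param object A `cpann` model.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cpann
#' @export
autoplot.cpann <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$output_weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "output",
                  title = sprintf("CP-ANN output layer (%s)", object$task)) +
    ggplot2::theme_minimal()
}
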