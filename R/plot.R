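#' Plot per-group score distributions
#'
#' Histograms of one score column, faceted or colored by a cell annotation —
#' the standard view for judging how well a signature separates labeled
#' populations.
#'
#' @param scores A `score_table` from [score_cells()].
#' @param ds The [expression_dataset()] the scores were computed on (supplies
#'   the annotation).
#' @param column Score column to plot; default the first score column.
#' @param by Annotation column used for fill (e.g. the ground-truth label).
#' @param bins Histogram bins (default 50).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, ds, column = NULL, by = NULL,
                                    bins = 50) {
  score_cols <- setdiff(names(scores), "cell_id")
  if (!length(score_cols)) abort("score table has no score columns")
  column <- column %||% score_cols[1]
  df <- dplyr::left_join(as_tibble(scores), ds$annotations, by = "cell_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[column]]))
  if (!is.null(by)) {
    p <- p + ggplot2::geom_histogram(
      ggplot2::aes(fill = .data[[by]]), bins = bins,
      position = "identity", alpha = 0.6)
  } else {
    p <- p + ggplot2::geom_histogram(bins = bins)
  }
  p + ggplot2::labs(x = column, y = "cells") + ggplot2::theme_minimal()
}

#' @rdname autoplot.robustness_curve
#' @export
plot_robustness_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$fraction, y = .data$auc,
                               color = factor(.data$K),
                               group = factor(.data$K))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::coord_cartesian(ylim = c(0.4, 1)) +
    ggplot2::labs(x = "fraction of counts kept", y = "AUC (marker set)",
                  color = "K") +
    ggplot2::theme_minimal()
}

#' Plot a downsampling robustness curve
#'
#' AUC against the fraction of counts kept, one line per smoothing level K
#' (K = 0 is unsmoothed). The x axis is reversed so robustness reads
#' left-to-right as deeper-to-shallower sequencing.
#'
#' @param object A `robustness_curve` from [run_robustness_curve()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot robustness_curve
#' @exportS3Method ggplot2::autoplot
autoplot.robustness_curve <- function(object, ...) {
  plot_robustness_curve(object, ...)
}
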