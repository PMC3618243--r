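# ggplot2 displays for evaluation reports, system comparisons and grids.

#' Plot an evaluation report
#'
#' Bars of precision / recall / F-measure per class, faceted by matching mode.
#'
#' @param object Tibble from [evaluate_spans()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ner_eval <- function(object, ...) {
  plot_eval(object)
}

#' @rdname autoplot.ner_eval
#' @param report Tibble from [evaluate_spans()].
#' @export
plot_eval <- function(report, ...) {
  long <- tidyr::pivot_longer(report,
                              cols = c("precision", "recall", "f_measure"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~mode) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ner_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$difference)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "paired F difference (A - B) per bootstrap replicate",
      y = "replicates",
      title = sprintf("Wilcoxon V = %.1f, p = %.3g", object$statistic,
                      object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot an experiment grid
#'
#' @param grid Result of [run_experiment_grid()].
#' @return A ggplot object: F-measure per feature set, grouped by algorithm,
#'   faceted by tag scheme.
#' @export
plot_grid_report <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$features, y = .data$f_measure,
                                     fill = .data$algorithm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::labs(x = NULL, y = "exact-match F (overall)", fill = NULL) +
    ggplot2::theme_minimal()
}
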