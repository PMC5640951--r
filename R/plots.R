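# ggplot2 displays for recall and discrimination results.

#' Box plots of recall distributions
#'
#' One box per (method, sub-dataset size), faceted by direction (and by
#' dataset when several are present) — the standard display for comparing
#' method consistency across sample sizes.
#'
#' @param object A `recall_result` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.recall_result <- function(object, ...) {
  facets <- if (dplyr::n_distinct(object$dataset) > 1) {
    ggplot2::facet_grid(ggplot2::vars(.data$dataset), ggplot2::vars(.data$direction))
  } else {
    ggplot2::facet_wrap(ggplot2::vars(.data$direction))
  }
  ggplot2::ggplot(
    object,
    ggplot2::aes(factor(.data$n), .data$recall, fill = .data$method)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    facets +
    ggplot2::labs(
      x = "sub-dataset size n", y = "recall",
      title = sprintf("Recall of top-%d pathways", object$K[1])
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Discrimination versus sub-dataset size
#'
#' @param object A `discrimination_result` tibble with `n` and `method`
#'   columns (from [run_discrimination_experiment()]).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.discrimination_result <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(factor(.data$n), .data$s, colour = .data$method, group = .data$method)
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$direction)) +
    ggplot2::labs(x = "sub-dataset size n", y = "discrimination s") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.recall_result
#' @export
plot_recall <- function(object, ...) autoplot.recall_result(object, ...)

#' @rdname autoplot.discrimination_result
#' @export
plot_discrimination <- function(object, ...) autoplot.discrimination_result(object, ...)
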