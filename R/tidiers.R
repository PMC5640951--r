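# broom-style tidiers for the package's result types.

#' Tidy a pathway ranking
#' @param x A `pathway_ranking`.
#' @param ... Ignored.
#' @return A plain tibble with columns `direction`, `rank`, `set_id`,
#'   `score`, `p_value`.
#' @export
tidy.pathway_ranking <- function(x, ...) {
  as_tibble(unclass2(x))
}

#' Tidy recall results
#' @param x A `recall_result` tibble.
#' @param ... Ignored.
#' @return A plain tibble, one row per (size, direction, replicate).
#' @export
tidy.recall_result <- function(x, ...) as_tibble(unclass2(x))

#' Summarize recall results
#' @param x A `recall_result` tibble.
#' @param ... Ignored.
#' @return One row per (dataset, method, direction, K, n) with the mean,
#'   standard deviation and replicate count of recall.
#' @export
glance.recall_result <- function(x, ...) {
  as_tibble(unclass2(x)) |>
    dplyr::group_by(.data$dataset, .data$method, .data$direction, .data$K, .data$n) |>
    dplyr::summarise(
      mean_recall = mean(.data$recall),
      sd_recall = sd(.data$recall),
      M = dplyr::n(),
      .groups = "drop"
    )
}

#' Tidy discrimination results
#' @param x A `discrimination_result` tibble.
#' @param ... Ignored.
#' @return A plain tibble.
#' @export
tidy.discrimination_result <- function(x, ...) as_tibble(unclass2(x))

#' Summarize discrimination results
#' @param x A `discrimination_result` tibble.
#' @param ... Ignored.
#' @return One row per result with the correct/total counts and `s`.
#' @export
glance.discrimination_result <- function(x, ...) as_tibble(unclass2(x))

# strip the package's S3 class tags, keep the tibble classes
unclass2 <- function(x) {
  class(x) <- setdiff(
    class(x),
    c("pathway_ranking", "recall_result", "discrimination_result")
  )
  attr(x, "K") <- NULL
  x
}
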