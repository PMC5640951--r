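# Configuration-driven end-to-end benchmark runs: simulate/load datasets,
# rank with each method, evaluate recall and discrimination, write tidy
# outputs.

#' Configure a benchmark run
#'
#' @param datasets A list of [expression_dataset()]s and/or
#'   [synthetic_design()]s (designs are generated against the collection at
#'   run time). At least one required.
#' @param collection A [geneset_collection()] or a path to a GMT file.
#' @param methods Character vector of method variant names, or a list of
#'   [method_config()]s. At least one required.
#' @param sizes Sub-dataset sizes.
#' @param M Replicates per size.
#' @param K Vector of top-list lengths.
#' @param seed Master seed for the whole run.
#' @param allocation Cohort allocation rule, see [allocate_cohorts()].
#' @param B Permutation count applied to name-specified methods.
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(datasets, collection, methods = "afc",
                             sizes = c(6, 12, 24, 48), M = 500,
                             K = c(20, 50), seed = 1L,
                             allocation = "stratified", B = 1000) {
  if (length(datasets) < 1L) abort("At least one dataset is required.")
  if (length(methods) < 1L) abort("At least one method is required.")
  if (is.character(methods)) {
    methods <- lapply(methods, method_config, B = B)
  }
  structure(
    list(
      datasets = datasets, collection = collection, methods = methods,
      sizes = sizes, M = M, K = K, seed = as.integer(seed),
      allocation = allocation
    ),
    class = "benchmark_config"
  )
}

#' Read a benchmark configuration from YAML
#'
#' Expected top-level keys: `datasets` (list of either
#' `{id, matrix, phenotype}` file references or `{id, synthetic: {...}}`
#' designs whose `synthetic` block takes the arguments of
#' [synthetic_design()]), `collection` (GMT path), `methods`, `sizes`, `M`,
#' `K`, `seed`, and optionally `allocation` and `B`.
#'
#' @param path Path to a YAML file.
#' @return A [benchmark_config()].
#' @export
read_benchmark_config <- function(path) {
  y <- yaml::read_yaml(path)
  datasets <- lapply(y$datasets, function(d) {
    if (!is.null(d$synthetic)) {
      do.call(synthetic_design, c(d$synthetic, list(id = d$id %||% "synthetic")))
    } else {
      read_expression(d$matrix, d$phenotype, id = d$id %||% basename(d$matrix))
    }
  })
  benchmark_config(
    datasets = datasets,
    collection = y$collection,
    methods = unlist(y$methods) %||% "afc",
    sizes = unlist(y$sizes) %||% c(6, 12, 24, 48),
    M = y$M %||% 500,
    K = unlist(y$K) %||% c(20, 50),
    seed = y$seed %||% 1L,
    allocation = y$allocation %||% "stratified",
    B = y$B %||% 1000
  )
}

resolve_collection <- function(collection) {
  if (inherits(collection, "geneset_collection")) collection else read_gmt(collection)
}

resolve_datasets <- function(datasets, coll) {
  out <- lapply(datasets, function(d) {
    if (inherits(d, "synthetic_design")) generate_dataset(d, coll) else d
  })
  setNames(out, vapply(out, `[[`, character(1), "id"))
}

#' Run a full benchmark
#'
#' For every (dataset, method, K) cell, runs the recall experiment over the
#' configured sizes; for every unordered dataset pair, the discrimination
#' experiment. Deterministic under the master seed; replicates are keyed by
#' replicate index, so results are invariant to execution order. When
#' `out_dir` is given, writes `recall.csv`, `discrimination.csv` and
#' `summary.json` (per-cell mean recall and the discrimination fractions).
#'
#' @param cfg A [benchmark_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return A list with tibbles `recall` and `discrimination` (the latter
#'   `NULL` for single-dataset configs) and the summary list, invisibly when
#'   writing.
#' @export
run_benchmark <- function(cfg, out_dir = NULL) {
  coll <- resolve_collection(cfg$collection)
  datasets <- resolve_datasets(cfg$datasets, coll)
  grid <- tidyr::expand_grid(
    dataset = names(datasets),
    method = seq_along(cfg$methods),
    K = cfg$K
  )
  recall_tbl <- purrr::pmap_dfr(grid, function(dataset, method, K) {
    inform(sprintf(
      "recall: dataset=%s method=%s K=%d",
      dataset, cfg$methods[[method]]$method, K
    ))
    run_recall_experiment(
      datasets[[dataset]], coll, cfg$methods[[method]],
      sizes = cfg$sizes, M = cfg$M, K = K,
      master_seed = cfg$seed, allocation = cfg$allocation
    )
  })
  disc_tbl <- NULL
  if (length(datasets) >= 2L) {
    pairs <- utils::combn(names(datasets), 2, simplify = FALSE)
    pair_grid <- tidyr::expand_grid(
      pair = seq_along(pairs),
      method = seq_along(cfg$methods),
      K = cfg$K
    )
    disc_tbl <- purrr::pmap_dfr(pair_grid, function(pair, method, K) {
      ids <- pairs[[pair]]
      inform(sprintf(
        "discrimination: %s vs %s method=%s K=%d",
        ids[1], ids[2], cfg$methods[[method]]$method, K
      ))
      run_discrimination_experiment(
        datasets[[ids[1]]], datasets[[ids[2]]], coll, cfg$methods[[method]],
        sizes = cfg$sizes, M = cfg$M, K = K,
        master_seed = cfg$seed, allocation = cfg$allocation
      )
    })
  }
  summary <- list(
    mean_recall = summarize_benchmark(recall_tbl),
    discrimination = disc_tbl
  )
  results <- list(recall = recall_tbl, discrimination = disc_tbl, summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(recall_tbl, file.path(out_dir, "recall.csv"), progress = FALSE)
    if (!is.null(disc_tbl)) {
      readr::write_csv(disc_tbl, file.path(out_dir, "discrimination.csv"), progress = FALSE)
    }
    jsonlite::write_json(
      summary, file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    return(invisible(results))
  }
  results
}

#' Summarize recall results as a mean-recall table with extrema flags
#'
#' For each (dataset, direction, K, n) cell, the mean recall per method,
#' with the row-wise best and worst methods flagged (`is_max` / `is_min`;
#' ties all flagged) — the machine-readable analogue of a methods x sizes
#' summary table.
#'
#' @param recall_tbl A `recall_result` tibble from
#'   [run_recall_experiment()] or [run_benchmark()].
#' @return A tibble with columns `dataset`, `direction`, `K`, `n`, `method`,
#'   `mean_recall`, `is_max`, `is_min`.
#' @export
summarize_benchmark <- function(recall_tbl) {
  if (is.null(recall_tbl) || nrow(recall_tbl) == 0L) {
    abort("No recall results to summarize.")
  }
  recall_tbl |>
    dplyr::group_by(.data$dataset, .data$direction, .data$K, .data$n, .data$method) |>
    dplyr::summarise(mean_recall = mean(.data$recall), .groups = "drop") |>
    dplyr::group_by(.data$dataset, .data$direction, .data$K, .data$n) |>
    dplyr::mutate(
      is_max = .data$mean_recall == max(.data$mean_recall),
      is_min = .data$mean_recall == min(.data$mean_recall)
    ) |>
    dplyr::ungroup()
}
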