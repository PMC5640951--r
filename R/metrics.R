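# The two evaluation metrics: recall (consistency of top-K lists between a
# dataset and its sub-datasets) and discrimination (fraction of sub-datasets
# correctly associated with their parent rather than another condition).

#' Recall of a sub-dataset ranking against the full-dataset ranking
#'
#' `r(A, a) = |A intersect a| / |A|`: the fraction of pathways identified
#' from the full dataset that are recovered from the sub-dataset. Both
#' arguments are same-direction top-K id lists, treated as sets.
#'
#' @param A Pathway ids from the full dataset (non-empty).
#' @param a Pathway ids from the sub-dataset.
#' @return A fraction in `[0, 1]`.
#' @export
recall <- function(A, a) {
  if (length(A) == 0L) abort("`A` must be non-empty: recall is undefined.")
  length(intersect(A, a)) / length(unique(A))
}

#' Discrimination between two conditions
#'
#' Given full-dataset rankings `A` and `A_prime` from two different
#' conditions and `M` sub-dataset rankings resampled from each, a
#' sub-dataset of the first condition is correctly associated iff
#' `r(A, a_i) > r(A_prime, a_i)` strictly (and symmetrically for the
#' second); ties count as incorrect, so two conditions with identical
#' rankings have discrimination 0. The discrimination `s` is the number of
#' correct associations divided by the total `2M`.
#'
#' @param A,A_prime Full-dataset pathway id lists for the two conditions.
#' @param a_list,a_list_prime Lists (length `M` each) of sub-dataset pathway
#'   id vectors resampled from the first and second condition.
#' @return A one-row tibble of class `discrimination_result` with columns
#'   `correct`, `total`, `s`.
#' @export
discrimination <- function(A, A_prime, a_list, a_list_prime) {
  if (length(a_list) != length(a_list_prime)) {
    abort("`a_list` and `a_list_prime` must contain the same number of sub-dataset rankings.")
  }
  if (length(a_list) < 1L) abort("At least one sub-dataset ranking per condition is required.")
  correct_a <- sum(vapply(
    a_list, function(a) recall(A, a) > recall(A_prime, a), logical(1)
  ))
  correct_ap <- sum(vapply(
    a_list_prime, function(a) recall(A_prime, a) > recall(A, a), logical(1)
  ))
  total <- 2L * length(a_list)
  out <- tibble(
    correct = correct_a + correct_ap,
    total = total,
    s = (correct_a + correct_ap) / total
  )
  class(out) <- c("discrimination_result", class(out))
  out
}

#' Discrimination generalized to more than two conditions
#'
#' A sub-dataset ranking is correctly associated iff its recall with its
#' parent dataset's list strictly exceeds its recall with every other
#' dataset's list.
#'
#' @param entries A list with one element per condition, each a list with
#'   elements `A` (full-dataset pathway ids) and `a_list` (list of
#'   sub-dataset pathway id vectors).
#' @return A one-row `discrimination_result` tibble.
#' @export
generalized_discrimination <- function(entries) {
  if (length(entries) < 2L) abort("At least 2 datasets are required.")
  correct <- 0L
  total <- 0L
  for (j in seq_along(entries)) {
    A_j <- entries[[j]]$A
    others <- lapply(entries[-j], `[[`, "A")
    for (a in entries[[j]]$a_list) {
      r_parent <- recall(A_j, a)
      total <- total + 1L
      if (all(vapply(others, function(B) r_parent > recall(B, a), logical(1)))) {
        correct <- correct + 1L
      }
    }
  }
  out <- tibble(correct = correct, total = total, s = correct / total)
  class(out) <- c("discrimination_result", class(out))
  out
}

# Sizes a method variant can handle: sample-label permutation needs >= 3
# samples per cohort in the sub-dataset.
usable_sizes <- function(sizes, cfg, allocation, n1, n2) {
  keep <- vapply(sizes, function(n) {
    alloc <- allocate_cohorts(n, n1, n2, allocation)
    !(uses_sample_permutation(cfg) && min(alloc) < 3L)
  }, logical(1))
  if (any(!keep)) {
    warn(sprintf(
      "Skipping size(s) %s for %s: fewer than 3 samples per cohort leaves too few distinct sample-label assignments.",
      paste(sizes[!keep], collapse = ", "), cfg$method
    ))
  }
  sizes[keep]
}

method_label <- function(cfg) if (is.function(cfg)) "custom" else cfg$method

# Rank a dataset with either a method_config or a custom ranker function
# (signature function(D, coll, K, seed) -> pathway_ranking).
rank_with <- function(cfg, D, coll, K, seed) {
  if (is.function(cfg)) {
    cfg(D, coll, K, seed)
  } else {
    cfg$seed <- seed
    pa_rank(D, coll, cfg, K = K)
  }
}

# Rank M sub-datasets of one size; returns a list of pathway_rankings.
subsample_rankings <- function(D, coll, cfg, n, M, K, master_seed, allocation) {
  n1 <- sum(D$cohort == "treatment")
  n2 <- sum(D$cohort == "control")
  alloc <- allocate_cohorts(n, n1, n2, allocation)
  lapply(seq_len(M), function(i) {
    sub_seed <- derive_seed(master_seed, D$id, method_label(cfg), n, i)
    d <- subsample(D, subsample_spec(alloc[1], alloc[2], seed = sub_seed, replicate_index = i))
    rank_with(cfg, d, coll, K, derive_seed(sub_seed, "rank"))
  })
}

#' Run the recall experiment for one dataset and one method
#'
#' Computes the full-dataset top-K lists `A` once, then for each sub-dataset
#' size draws `M` stratified sub-datasets, ranks each, and records the
#' recall per direction. Sizes that leave fewer than 3 samples per cohort
#' are skipped with a warning for sample-label permutation methods.
#'
#' @param D An [expression_dataset()] (the large original dataset).
#' @param coll A [geneset_collection()].
#' @param cfg A [method_config()], a method name, or a custom ranker
#'   function with signature `function(D, coll, K, seed)` returning a
#'   `pathway_ranking` (useful for baseline stubs).
#' @param sizes Sub-dataset sizes, each smaller than `ncol(D$values)`.
#' @param M Number of sub-dataset replicates per size.
#' @param K Top-list length per direction.
#' @param master_seed Master seed; each replicate derives its own stream.
#' @param allocation Cohort allocation rule, see [allocate_cohorts()].
#' @return A `recall_result` tibble with columns `dataset`, `method`,
#'   `direction`, `K`, `n`, `replicate`, `recall`.
#' @export
run_recall_experiment <- function(D, coll, cfg, sizes = c(6, 12, 24, 48),
                                  M = 500, K = 20, master_seed = 1L,
                                  allocation = c("stratified", "proportional")) {
  allocation <- match.arg(allocation)
  if (is.character(cfg)) cfg <- method_config(cfg)
  if (any(sizes >= ncol(D$values))) {
    abort("Every sub-dataset size must be smaller than the dataset.")
  }
  n1 <- sum(D$cohort == "treatment")
  n2 <- sum(D$cohort == "control")
  if (!is.function(cfg)) sizes <- usable_sizes(sizes, cfg, allocation, n1, n2)
  A <- rank_with(
    cfg, D, coll, K,
    derive_seed(master_seed, D$id, method_label(cfg), "full")
  )
  rows <- purrr::map_dfr(sizes, function(n) {
    subs <- subsample_rankings(D, coll, cfg, n, M, K, master_seed, allocation)
    purrr::map_dfr(c("up", "down"), function(dir) {
      tibble(
        dataset = D$id,
        method = method_label(cfg),
        direction = dir,
        K = as.integer(K),
        n = as.integer(n),
        replicate = seq_len(M),
        recall = vapply(
          subs,
          function(a) recall(ranking_ids(A, dir), ranking_ids(a, dir)),
          numeric(1)
        )
      )
    })
  })
  class(rows) <- c("recall_result", class(rows))
  rows
}

#' Run the discrimination experiment for a dataset pair and one method
#'
#' Computes `A` and `A_prime` from the two full datasets, resamples `M`
#' sub-datasets of each size from each dataset (unmatched draws), and
#' evaluates [discrimination()] per size and direction.
#'
#' @param D,D_prime Two [expression_dataset()]s from different conditions.
#' @inheritParams run_recall_experiment
#' @return A `discrimination_result` tibble with columns `dataset`,
#'   `dataset_prime`, `method`, `direction`, `K`, `n`, `correct`, `total`,
#'   `s`.
#' @export
run_discrimination_experiment <- function(D, D_prime, coll, cfg,
                                          sizes = c(6, 12, 24, 48), M = 500,
                                          K = 20, master_seed = 1L,
                                          allocation = c("stratified", "proportional")) {
  allocation <- match.arg(allocation)
  if (is.character(cfg)) cfg <- method_config(cfg)
  for (dd in list(D, D_prime)) {
    if (any(sizes >= ncol(dd$values))) {
      abort("Every sub-dataset size must be smaller than both datasets.")
    }
  }
  if (!is.function(cfg)) {
    sizes <- usable_sizes(
      sizes, cfg, allocation,
      min(sum(D$cohort == "treatment"), sum(D_prime$cohort == "treatment")),
      min(sum(D$cohort == "control"), sum(D_prime$cohort == "control"))
    )
  }
  A <- rank_with(
    cfg, D, coll, K,
    derive_seed(master_seed, D$id, method_label(cfg), "full")
  )
  A_prime <- rank_with(
    cfg, D_prime, coll, K,
    derive_seed(master_seed, D_prime$id, method_label(cfg), "full")
  )
  rows <- purrr::map_dfr(sizes, function(n) {
    subs <- subsample_rankings(D, coll, cfg, n, M, K, master_seed, allocation)
    subs_p <- subsample_rankings(D_prime, coll, cfg, n, M, K, master_seed, allocation)
    purrr::map_dfr(c("up", "down"), function(dir) {
      d <- discrimination(
        ranking_ids(A, dir), ranking_ids(A_prime, dir),
        lapply(subs, ranking_ids, direction = dir),
        lapply(subs_p, ranking_ids, direction = dir)
      )
      dplyr::mutate(
        d,
        dataset = D$id, dataset_prime = D_prime$id, method = method_label(cfg),
        direction = dir, K = as.integer(K), n = as.integer(n),
        .before = 1
      )
    })
  })
  class(rows) <- c("discrimination_result", class(rows))
  rows
}

#' Top-K overlap between a small and a large dataset of the same condition
#'
#' Ranks both full datasets and returns, per direction, the proportion of
#' the large dataset's top-K pathways also identified for the small dataset
#' — `recall(A_large, A_small)`, the cross-study analogue of resampling
#' recall.
#'
#' @param D_small,D_large Two [expression_dataset()]s of the same condition.
#' @param coll A [geneset_collection()].
#' @param cfg A [method_config()] (or method name).
#' @param K Top-list length per direction (50 is the usual cross-study
#'   choice).
#' @param master_seed Seed for the permutation nulls.
#' @return A tibble with columns `direction`, `overlap`.
#' @export
cross_dataset_overlap <- function(D_small, D_large, coll, cfg, K = 50,
                                  master_seed = 1L) {
  if (is.character(cfg)) cfg <- method_config(cfg)
  A_small <- rank_with(
    cfg, D_small, coll, K,
    derive_seed(master_seed, D_small$id, method_label(cfg), "full")
  )
  A_large <- rank_with(
    cfg, D_large, coll, K,
    derive_seed(master_seed, D_large$id, method_label(cfg), "full")
  )
  tibble(
    direction = c("up", "down"),
    overlap = vapply(
      c("up", "down"),
      function(dir) recall(ranking_ids(A_large, dir), ranking_ids(A_small, dir)),
      numeric(1), USE.NAMES = FALSE
    )
  )
}

#' Uniformly random top-K ranking (baseline stub)
#'
#' Emits a uniformly random K-subset of the pathway ids in both directions.
#' Useful as a null baseline: against a fixed list `A` of the same `K`, its
#' expected recall is `K / P` for a collection of `P` pathways.
#'
#' @param set_ids Pathway ids to draw from.
#' @param K List length per direction.
#' @param seed Seed of the draw.
#' @return A `pathway_ranking` tibble.
#' @export
random_ranking <- function(set_ids, K, seed = 1L) {
  check_scalar_int(K, "K", min = 1)
  if (K > length(set_ids)) abort("`K` exceeds the number of pathways.")
  withr::with_seed(seed, {
    out <- dplyr::bind_rows(
      tibble(direction = "up", rank = seq_len(K), set_id = sample(set_ids, K)),
      tibble(direction = "down", rank = seq_len(K), set_id = sample(set_ids, K))
    )
  })
  out$score <- NA_real_
  out$p_value <- NA_real_
  attr(out, "K") <- as.integer(K)
  class(out) <- c("pathway_ranking", class(out))
  out
}
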