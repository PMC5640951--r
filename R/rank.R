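# Method configuration, top-K ranking, and the user-facing pa_rank() that
# maps a dataset + collection to ranked up-/down-regulated pathway lists.

#' Configure a pathway-analysis method variant
#'
#' The six supported variants are `"ora"` (over-representation analysis,
#' hypergeometric, no permutation), `"gsa"` (maxmean with
#' restandardization), `"gsea"` / `"afc"` (gene-label permutation null) and
#' `"gseas"` / `"afcs"` (sample-label permutation null).
#'
#' @param method One of `"ora"`, `"gsa"`, `"gsea"`, `"gseas"`, `"afc"`,
#'   `"afcs"`.
#' @param B Number of permutations for the null (ignored by ORA). When the
#'   number of distinct sample-label assignments is at most `B`, all of them
#'   are enumerated exactly instead of sampled.
#' @param de_alpha Two-sided t-test p-value cutoff defining differentially
#'   expressed genes for ORA.
#' @param gsea_weight Exponent of the weighted Kolmogorov-Smirnov statistic
#'   (0 gives the classical unweighted KS statistic).
#' @param rank_by Statistic ordering the gene list for GSEA: the
#'   t-statistic (default) or the mean fold change.
#' @param welch Use Welch's t instead of the pooled-variance Student t.
#' @param gsa_random_sets Random gene sets per set size used to estimate the
#'   gene-randomization moments in GSA restandardization.
#' @param seed Seed for the permutation stream.
#' @return A `method_config` list.
#' @export
method_config <- function(method = c("ora", "gsa", "gsea", "gseas", "afc", "afcs"),
                          B = 1000, de_alpha = 0.05, gsea_weight = 1,
                          rank_by = c("t", "fold_change"), welch = FALSE,
                          gsa_random_sets = 200, seed = 1L) {
  method <- match.arg(method)
  check_scalar_int(B, "B", min = 1)
  if (!is.numeric(de_alpha) || de_alpha <= 0 || de_alpha >= 1) {
    abort("`de_alpha` must lie in (0, 1).")
  }
  base <- c(
    ora = "ora", gsa = "gsa", gsea = "gsea", gseas = "gsea",
    afc = "afc", afcs = "afc"
  )[[method]]
  mode <- c(
    ora = "none", gsa = "restandardization", gsea = "gene_label",
    gseas = "sample_label", afc = "gene_label", afcs = "sample_label"
  )[[method]]
  structure(
    list(
      method = method, base = base, permutation_mode = mode,
      B = as.integer(B), de_alpha = de_alpha, gsea_weight = gsea_weight,
      rank_by = match.arg(rank_by), welch = welch,
      gsa_random_sets = as.integer(gsa_random_sets), seed = as.integer(seed)
    ),
    class = "method_config"
  )
}

#' Does a method variant permute sample labels?
#' @param cfg A [method_config()].
#' @return `TRUE` for sample-label permutation and restandardization
#'   variants, which need at least 3 samples per cohort to give a useful
#'   null.
#' @export
uses_sample_permutation <- function(cfg) {
  cfg$permutation_mode %in% c("sample_label", "restandardization")
}

#' Select the top-K pathways per direction from a score table
#'
#' Pathways are sorted by ascending one-sided permutation p-value (`p_up`
#' for the up list, `p_down` for the down list), ties broken by descending
#' score magnitude, then lexicographic pathway id. For signed-score methods
#' a pathway is eligible only for the list matching its score's sign
#' (non-negative scores compete for the up list); ORA scores each direction
#' separately, so a pathway may appear in both lists.
#'
#' @param table A score table: tibble with columns `set_id`, `p_up`,
#'   `p_down`, and either `score` (signed methods) or `score_up` /
#'   `score_down` (direction-specific tie-break magnitudes).
#' @param K Maximum list length per direction.
#' @param signed Whether scores are signed (one list per pathway).
#' @return A `pathway_ranking`: tibble with columns `direction`
#'   (`"up"`/`"down"`), `rank`, `set_id`, `score`, `p_value`.
#' @export
rank_top_k <- function(table, K, signed = TRUE) {
  check_scalar_int(K, "K", min = 1)
  if (K > nrow(table)) {
    warn(sprintf(
      "K = %d exceeds the %d available pathways; returning all.",
      K, nrow(table)
    ))
  }
  pick <- function(direction) {
    p <- if (direction == "up") table$p_up else table$p_down
    if (signed) {
      mag <- abs(table$score)
      eligible <- if (direction == "up") table$score >= 0 else table$score < 0
      score <- table$score
    } else {
      score <- if (direction == "up") table$score_up else table$score_down
      mag <- abs(score)
      eligible <- rep(TRUE, nrow(table))
    }
    ord <- order(p, -mag, table$set_id)
    ord <- ord[eligible[ord]]
    ord <- head(ord, K)
    tibble(
      direction = direction,
      rank = seq_along(ord),
      set_id = table$set_id[ord],
      score = score[ord],
      p_value = p[ord]
    )
  }
  out <- dplyr::bind_rows(pick("up"), pick("down"))
  attr(out, "K") <- as.integer(K)
  class(out) <- c("pathway_ranking", class(out))
  out
}

#' Pathway ids of one direction of a ranking
#' @param ranking A `pathway_ranking` from [rank_top_k()] or [pa_rank()].
#' @param direction `"up"` or `"down"`.
#' @return Character vector of pathway ids, most significant first.
#' @export
ranking_ids <- function(ranking, direction = c("up", "down")) {
  direction <- match.arg(direction)
  ranking$set_id[ranking$direction == direction]
}

#' Rank pathways for a dataset with one method variant
#'
#' The one-call interface: restricts the collection to the measured genes,
#' scores every pathway, computes permutation p-values where the method
#' needs them, and returns the top-K up- and down-regulated pathway lists.
#'
#' @param D An [expression_dataset()].
#' @param coll A [geneset_collection()].
#' @param method Method variant name, or a full [method_config()].
#' @param K List length per direction (the benchmarking convention fixes K,
#'   typically 20 or 50, rather than a significance threshold).
#' @param ... Passed to [method_config()] when `method` is a name.
#' @return A `pathway_ranking` (see [rank_top_k()]).
#' @examples
#' coll <- block_collection(n_sets = 10, set_size = 10)
#' design <- synthetic_design(
#'   n_genes = 100, n_treatment = 10, n_control = 10,
#'   perturbed = list(S01 = list(delta = 2)), seed = 1
#' )
#' D <- generate_dataset(design, coll)
#' pa_rank(D, coll, "afc", K = 3, B = 100, seed = 1)
#' @export
pa_rank <- function(D, coll, method = "afc", K = 20, ...) {
  cfg <- if (inherits(method, "method_config")) method else method_config(method, ...)
  measured <- rownames(D$values)
  rcoll <- suppressWarnings(restrict_to_measured(coll, measured))
  if (nrow(rcoll) == 0L) abort("No gene set overlaps the measured genes.")
  table <- if (cfg$base == "ora") {
    ora_scores(D, rcoll, cfg)
  } else {
    permutation_pvalues(D, rcoll, scorer = cfg$base, cfg = cfg)
  }
  rank_top_k(table, K, signed = cfg$base != "ora")
}
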