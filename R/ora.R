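# Over-representation analysis: hypergeometric test of the overlap between
# differentially expressed genes and each pathway.

#' Over-representation score table
#'
#' Identifies differentially expressed (DE) genes as those with a two-sided
#' t-test p-value below `cfg$de_alpha`, splits them by the sign of the
#' t-statistic into up- and down-regulated lists, and tests each pathway for
#' over-representation of each list with a hypergeometric upper-tail
#' probability (the chance of observing at least the seen overlap). The
#' universe is the set of measured genes that appear in the collection.
#'
#' @param D An [expression_dataset()].
#' @param coll A [geneset_collection()] already restricted to measured genes.
#' @param cfg A [method_config()] with `method = "ora"`.
#' @return A tibble with columns `set_id`, `score_up`, `score_down` (the
#'   overlap counts, used for tie-breaking), `p_up`, `p_down`.
#' @export
ora_scores <- function(D, coll, cfg = method_config("ora")) {
  stats <- compute_gene_stats(D, welch = cfg$welch)
  universe <- intersect(stats$gene_id, gene_universe(coll))
  de <- stats$gene_id[stats$p_value < cfg$de_alpha]
  de_up <- intersect(de[stats$t[match(de, stats$gene_id)] > 0], universe)
  de_down <- intersect(de[stats$t[match(de, stats$gene_id)] < 0], universe)
  if (length(de_up) == 0L || length(de_down) == 0L) {
    inform("No differentially expressed genes in at least one direction; that direction ranks on p = 1.")
  }
  U <- length(universe)
  tail_p <- function(members, de_dir) {
    m <- length(members)
    k <- length(intersect(members, de_dir))
    K_de <- length(de_dir)
    # P(overlap >= k) drawing m genes from U with K_de marked
    phyper(k - 1, K_de, U - K_de, m, lower.tail = FALSE)
  }
  members <- lapply(coll$genes, intersect, universe)
  tibble(
    set_id = coll$set_id,
    score_up = vapply(members, function(g) length(intersect(g, de_up)), numeric(1)),
    score_down = vapply(members, function(g) length(intersect(g, de_down)), numeric(1)),
    p_up = vapply(members, tail_p, numeric(1), de_dir = de_up),
    p_down = vapply(members, tail_p, numeric(1), de_dir = de_down)
  )
}
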