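# Pathway-level score statistics: aggregate fold change, GSA maxmean, and
# the weighted Kolmogorov-Smirnov enrichment score of GSEA.

#' Aggregate fold change (AFC) pathway score
#'
#' The arithmetic mean of the per-gene mean fold changes over the member
#' genes of a pathway. Positive scores indicate up-regulation in the
#' treatment cohort.
#'
#' @param stats A gene-statistics tibble from [compute_gene_stats()].
#' @param genes Character vector of member gene symbols (already restricted
#'   to measured genes, non-empty).
#' @return A single signed score.
#' @export
afc_score <- function(stats, genes) {
  idx <- match(genes, stats$gene_id)
  if (anyNA(idx)) abort("All member genes must be present in `stats`.")
  if (length(idx) == 0L) abort("`genes` must be non-empty.")
  mean(stats$fold_change[idx])
}

#' GSA maxmean pathway score
#'
#' Splits the member genes' signed scores `z` (here the per-gene
#' t-statistics) into positive and negative parts, averages each part over
#' all member genes, and returns the part with the larger absolute value:
#' `s+ = mean(max(z, 0))`, `s- = mean(max(-z, 0))`; the score is `+s+` if
#' `s+ > s-`, else `-s-`.
#'
#' @inheritParams afc_score
#' @return A single signed score.
#' @export
gsa_maxmean <- function(stats, genes) {
  idx <- match(genes, stats$gene_id)
  if (anyNA(idx)) abort("All member genes must be present in `stats`.")
  if (length(idx) == 0L) abort("`genes` must be non-empty.")
  maxmean_from_z(stats$t[idx])
}

maxmean_from_z <- function(z) {
  s_pos <- mean(pmax(z, 0))
  s_neg <- mean(pmax(-z, 0))
  if (s_pos > s_neg) s_pos else -s_neg
}

#' Weighted Kolmogorov-Smirnov enrichment score (GSEA)
#'
#' Walks the ranked gene list accumulating a running sum that increases by
#' `|stat|^p / sum_hits |stat|^p` at member genes ("hits") and decreases by
#' `1 / (N - N_hits)` at non-members ("misses"); the enrichment score ES is
#' the running-sum value of maximal absolute deviation from zero, keeping
#' its sign. With `p = 0` this is the classical unweighted KS statistic.
#' If every hit weight is zero (possible when `p > 0` and all member
#' statistics are exactly zero), hits are weighted equally.
#'
#' @param ranked_genes Character vector: all measured genes in rank order
#'   (most treatment-up-regulated first).
#' @param weights Per-gene statistic magnitudes aligned with `ranked_genes`
#'   (the exponent is applied here).
#' @param genes Member genes of the set (non-empty after restriction; must
#'   not contain every measured gene).
#' @param p Weight exponent (GSEA default 1).
#' @return The signed enrichment score.
#' @export
gsea_enrichment_score <- function(ranked_genes, weights, genes, p = 1) {
  hits <- which(ranked_genes %in% genes)
  if (length(hits) == 0L) abort("`genes` has no overlap with `ranked_genes`.")
  if (length(hits) == length(ranked_genes)) {
    abort("Gene set contains every measured gene; the miss decrement is undefined.")
  }
  es_from_positions(hits, abs(weights[hits])^p, length(ranked_genes))
}

# Fast ES kernel. pos: sorted hit positions in 1..N; w: hit weights in the
# same order. The running sum is piecewise linear between hits, so its
# extrema occur at a hit (maximum candidates) or just before one (minimum
# candidates); the end value is 0.
es_from_positions <- function(pos, w, N) {
  n_hits <- length(pos)
  n_miss <- N - n_hits
  total <- sum(w)
  if (total <= 0) {
    w <- rep(1, n_hits)
    total <- n_hits
  }
  hit_cum <- cumsum(w) / total
  miss_cum <- (pos - seq_len(n_hits)) / n_miss
  # candidates are bounded by 1; rounding keeps the positive-on-tie rule
  # stable against floating-point accumulation
  top <- round(hit_cum - miss_cum, 12)         # value at each hit position
  bottom <- round(c(0, hit_cum[-n_hits]) - miss_cum, 12) # just before each hit
  es_pos <- max(top)
  es_neg <- min(bottom, 0)
  if (es_pos >= -es_neg) es_pos else es_neg
}
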