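# Per-gene differential-expression statistics for a two-cohort dataset.

#' Per-gene two-sample statistics
#'
#' Computes, for every gene, the pooled-variance (Student) two-sample
#' t-statistic with its two-sided p-value, and the mean fold change —
#' treatment mean minus control mean of the (already log2-scale) expression
#' values. Genes with zero pooled variance but a non-zero mean difference
#' get `t = +/-Inf` and `p = 0`; genes with zero variance and zero
#' difference get `t = 0`, `p = 1`. Welch's unequal-variance t is available
#' by flag.
#'
#' @param D An [expression_dataset()].
#' @param welch Use Welch's t instead of the pooled-variance Student t.
#' @return A tibble with columns `gene_id`, `t`, `p_value`, `fold_change`,
#'   one row per gene in the order of the dataset.
#' @export
compute_gene_stats <- function(D, welch = FALSE) {
  X <- D$values
  tr <- D$cohort == "treatment"
  n1 <- sum(tr)
  n2 <- sum(!tr)
  m1 <- rowMeans(X[, tr, drop = FALSE])
  m2 <- rowMeans(X[, !tr, drop = FALSE])
  v1 <- rowSums((X[, tr, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((X[, !tr, drop = FALSE] - m2)^2) / (n2 - 1)
  diff <- m1 - m2
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
    tt <- diff / sqrt(se2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    tt <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  degenerate <- !is.finite(tt)
  if (any(degenerate)) {
    tt[degenerate] <- sign(diff[degenerate]) * Inf
    tt[degenerate & diff == 0] <- 0
    inform(sprintf(
      "%d gene(s) with zero within-group variance; t set by convention.",
      sum(degenerate)
    ))
  }
  p <- 2 * pt(-abs(tt), df = df)
  p[tt == 0 & degenerate] <- 1
  tibble(
    gene_id = rownames(X),
    t = unname(tt),
    p_value = unname(p),
    fold_change = unname(diff)
  )
}

# Batch t / fold-change over many label assignments at once.
# labels: logical matrix (samples x B), TRUE = treatment. Returns list of
# genes x B matrices `t` and `fold_change`. Used by sample-label permutation.
batch_gene_stats <- function(X, labels, welch = FALSE) {
  N <- ncol(X)
  n1 <- colSums(labels)
  n2 <- N - n1
  W1 <- sweep(labels, 2, n1, "/")
  W0 <- sweep(!labels, 2, n2, "/")
  X2 <- X^2
  M1 <- X %*% W1
  M2 <- X %*% W0
  # unbiased variances via E[x^2] - mean^2
  V1 <- sweep((X2 %*% W1 - M1^2), 2, n1 / (n1 - 1), "*")
  V2 <- sweep((X2 %*% W0 - M2^2), 2, n2 / (n2 - 1), "*")
  V1[V1 < 0] <- 0
  V2[V2 < 0] <- 0
  diff <- M1 - M2
  if (welch) {
    se2 <- sweep(V1, 2, n1, "/") + sweep(V2, 2, n2, "/")
    tt <- diff / sqrt(se2)
  } else {
    sp2 <- sweep(
      sweep(V1, 2, n1 - 1, "*") + sweep(V2, 2, n2 - 1, "*"),
      2, n1 + n2 - 2, "/"
    )
    tt <- diff / sweep(sqrt(sp2), 2, sqrt(1 / n1 + 1 / n2), "*")
  }
  bad <- !is.finite(tt)
  if (any(bad)) {
    tt[bad] <- sign(diff[bad]) * Inf
    tt[bad & diff == 0] <- 0
  }
  list(t = tt, fold_change = diff)
}
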