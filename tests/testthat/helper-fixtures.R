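# Shared fixtures and independent oracles for the test suite.

# small collection: 4 sets over 10 genes
tiny_collection <- function() {
  geneset_collection(
    set_id = c("P1", "P2", "P3", "P4"),
    name = "tiny",
    genes = list(
      c("g1", "g2", "g3"),
      c("g3", "g4", "g5"),
      c("g6", "g7"),
      c("g8", "g9", "g10")
    )
  )
}

# dataset from an explicit matrix; cohort defaults to first half treatment
make_dataset <- function(values, n_treatment = ncol(values) / 2, id = "toy") {
  expression_dataset(
    values,
    rep(c("treatment", "control"), c(n_treatment, ncol(values) - n_treatment)),
    id = id
  )
}

random_dataset <- function(n_genes = 40, n_treatment = 5, n_control = 5,
                           seed = 1, id = "rand") {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n_genes * (n_treatment + n_control), mean = 7),
      n_genes, n_treatment + n_control,
      dimnames = list(
        sprintf("g%d", seq_len(n_genes)),
        sprintf("s%d", seq_len(n_treatment + n_control))
      )
    )
  })
  make_dataset(X, n_treatment, id = id)
}

# brute-force weighted KS enrichment score: explicit step-by-step running sum
brute_es <- function(ranked_genes, weights, genes, p = 1) {
  N <- length(ranked_genes)
  hit <- ranked_genes %in% genes
  w <- abs(weights)^p
  tot <- sum(w[hit])
  if (tot <= 0) {
    w[] <- 1
    tot <- sum(w[hit])
  }
  run <- 0
  vals <- numeric(N)
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) w[i] / tot else -1 / (N - sum(hit))
    vals[i] <- run
  }
  vals <- round(vals, 12) # guard the positive-on-tie rule against accumulation error
  es_pos <- max(vals)
  es_neg <- min(vals)
  if (es_pos >= -es_neg) es_pos else es_neg
}

# exhaustive hypergeometric upper tail: P(overlap >= k) when drawing a set of
# size m from a universe of U genes of which K_de are marked
brute_hyper_tail <- function(k, K_de, U, m) {
  ks <- seq(k, min(m, K_de))
  if (length(ks) == 0 || k <= 0) {
    return(1)
  }
  sum(choose(K_de, ks) * choose(U - K_de, m - ks)) / choose(U, m)
}

# independent enumeration of distinct label assignments: every C(N, n1)
# treatment subset, identifying each with its complement when n1 == n2
brute_distinct_assignments <- function(n1, n2) {
  combos <- combn(n1 + n2, n1, simplify = FALSE)
  keys <- vapply(combos, function(s) {
    key <- paste(s, collapse = ",")
    if (n1 == n2) {
      comp <- paste(setdiff(seq_len(n1 + n2), s), collapse = ",")
      key <- min(key, comp)
    }
    key
  }, character(1))
  length(unique(keys))
}

# a dataset engineered so the DE status of every gene is exact:
# `up`/`down` genes get a +/-5 shift with zero within-group variance
# (t = +/-Inf, p = 0); all other genes are identical across cohorts
# (t = 0, p = 1). Gene names g1..gU.
engineered_de_dataset <- function(U, up = character(), down = character(),
                                  n_per_cohort = 2) {
  genes <- sprintf("g%d", seq_len(U))
  base <- matrix(
    rep(seq_len(U), 2 * n_per_cohort),
    U, 2 * n_per_cohort,
    dimnames = list(genes, sprintf("s%d", seq_len(2 * n_per_cohort)))
  )
  base[genes %in% up, seq_len(n_per_cohort)] <-
    base[genes %in% up, seq_len(n_per_cohort)] + 5
  base[genes %in% down, seq_len(n_per_cohort)] <-
    base[genes %in% down, seq_len(n_per_cohort)] - 5
  suppressMessages(make_dataset(base, n_per_cohort, id = "engineered"))
}
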