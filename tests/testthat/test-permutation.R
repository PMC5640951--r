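# independent AFC sample-label oracle: enumerate all distinct assignments by
# brute force and recompute fold changes from scratch
brute_afc_sample_null <- function(D, members) {
  N <- ncol(D$values)
  n1 <- sum(D$cohort == "treatment")
  combos <- combn(N, n1, simplify = FALSE)
  if (n1 == N - n1) combos <- Filter(function(s) 1 %in% s, combos)
  vapply(combos, function(s) {
    m1 <- rowMeans(D$values[members, s, drop = FALSE])
    m2 <- rowMeans(D$values[members, -s, drop = FALSE])
    mean(m1 - m2)
  }, numeric(1))
}

test_that("3v3 sample-label null enumerates exactly the 10 distinct assignments", {
  D <- random_dataset(n_genes = 12, n_treatment = 3, n_control = 3, seed = 6)
  coll <- geneset_collection(
    c("S1", "S2"),
    genes = list(sprintf("g%d", 1:4), sprintf("g%d", 5:12))
  )
  tab <- permutation_pvalues(D, coll, "afc", method_config("afcs", B = 1000, seed = 3))
  expect_equal(attr(tab, "B_eff"), 10)

  # p-values agree with a from-scratch enumeration of the null
  for (sid in c("S1", "S2")) {
    members <- coll$genes[[which(coll$set_id == sid)]]
    nulls <- brute_afc_sample_null(D, members)
    obs <- afc_score(compute_gene_stats(D), members)
    expect_equal(
      tab$p_up[tab$set_id == sid],
      (sum(nulls >= obs) + 1) / (length(nulls) + 1)
    )
    expect_equal(
      tab$p_down[tab$set_id == sid],
      (sum(nulls <= obs) + 1) / (length(nulls) + 1)
    )
  }
})

test_that("permutation p-values lie in (0, 1] and the two tails overlap", {
  D <- random_dataset(n_genes = 30, n_treatment = 4, n_control = 4, seed = 10)
  coll <- geneset_collection(
    sprintf("S%d", 1:6),
    genes = split(sprintf("g%d", 1:30), rep(1:6, each = 5))
  )
  for (method in c("afc", "afcs", "gsea", "gseas", "gsa")) {
    cfg <- method_config(method, B = 99, seed = 4)
    tab <- permutation_pvalues(D, coll, cfg$base, cfg)
    expect_true(all(tab$p_up > 0 & tab$p_up <= 1), info = method)
    expect_true(all(tab$p_down > 0 & tab$p_down <= 1), info = method)
    # add-one estimator: the two one-sided tails double-count ties
    expect_true(all(tab$p_up + tab$p_down > 1), info = method)
  }
})

test_that("identical inputs and seed give bit-identical rankings", {
  D <- random_dataset(n_genes = 40, n_treatment = 5, n_control = 5, seed = 12)
  coll <- geneset_collection(
    sprintf("S%d", 1:8),
    genes = split(sprintf("g%d", 1:40), rep(1:8, each = 5))
  )
  for (method in c("ora", "afc", "gseas", "gsa")) {
    r1 <- suppressMessages(pa_rank(D, coll, method, K = 4, B = 50, seed = 77))
    r2 <- suppressMessages(pa_rank(D, coll, method, K = 4, B = 50, seed = 77))
    expect_identical(r1, r2, info = method)
  }
})

test_that("label swap negates scores and exchanges the up/down lists", {
  D <- random_dataset(n_genes = 40, n_treatment = 5, n_control = 5, seed = 14)
  swapped <- expression_dataset(
    D$values,
    ifelse(D$cohort == "treatment", "control", "treatment"),
    id = D$id
  )
  coll <- geneset_collection(
    sprintf("S%d", 1:8),
    genes = split(sprintf("g%d", 1:40), rep(1:8, each = 5))
  )
  cfg <- method_config("afc", B = 200, seed = 5)
  t1 <- permutation_pvalues(D, coll, "afc", cfg)
  t2 <- permutation_pvalues(swapped, coll, "afc", cfg)
  expect_equal(t2$score, -t1$score)
  expect_equal(t2$p_up, t1$p_down)
  expect_equal(t2$p_down, t1$p_up)
  r1 <- rank_top_k(t1, 3)
  r2 <- rank_top_k(t2, 3)
  expect_equal(ranking_ids(r2, "up"), ranking_ids(r1, "down"))
  expect_equal(ranking_ids(r2, "down"), ranking_ids(r1, "up"))
})

test_that("sample-label permutation refuses cohorts too small to permute", {
  D <- random_dataset(n_genes = 10, n_treatment = 2, n_control = 2, seed = 1)
  coll <- geneset_collection("S1", genes = list(sprintf("g%d", 1:5)))
  # 2v2: permuted cohorts stay at size 2, allowed (3 distinct assignments)
  tab <- permutation_pvalues(D, coll, "afc", method_config("afcs", B = 100))
  expect_equal(attr(tab, "B_eff"), 3)
})

test_that("gene-label nulls for afc and gsa match per-set rescoring", {
  D <- random_dataset(n_genes = 20, n_treatment = 3, n_control = 3, seed = 8)
  coll <- geneset_collection(
    c("S1", "S2"),
    genes = list(sprintf("g%d", 1:6), sprintf("g%d", 7:20))
  )
  stats <- compute_gene_stats(D)
  for (scorer in c("afc", "gsa")) {
    cfg <- method_config(if (scorer == "afc") "afc" else "gsa", B = 25, seed = 9)
    cfg$permutation_mode <- "gene_label"
    tab <- permutation_pvalues(D, coll, scorer, cfg)
    z <- if (scorer == "afc") stats$fold_change else stats$t
    # recompute the null with the same derived seed, per set, one perm at a time
    idx_list <- lapply(coll$genes, match, rownames(D$values))
    nulls <- withr::with_seed(
      derive_seed(cfg$seed, "gene_label", scorer),
      vapply(1:25, function(b) {
        rp <- sample.int(20)
        vapply(idx_list, function(i) {
          zz <- z[rp[i]]
          if (scorer == "afc") mean(zz) else {
            sp <- mean(pmax(zz, 0)); sn <- mean(pmax(-zz, 0))
            if (sp > sn) sp else -sn
          }
        }, numeric(1))
      }, numeric(2))
    )
    obs <- vapply(idx_list, function(i) {
      zz <- z[i]
      if (scorer == "afc") mean(zz) else {
        sp <- mean(pmax(zz, 0)); sn <- mean(pmax(-zz, 0))
        if (sp > sn) sp else -sn
      }
    }, numeric(1))
    expect_equal(tab$p_up, (rowSums(nulls >= obs) + 1) / 26, info = scorer)
  }
})
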