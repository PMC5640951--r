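test_that("recall is the recovered fraction of the full-dataset list", {
  A <- sprintf("P%d", 1:20)
  a <- c(sprintf("P%d", 1:10), sprintf("Q%d", 1:10))
  expect_equal(recall(A, a), 0.5)
  expect_equal(recall(A, A), 1.0)
  expect_equal(recall(A, sprintf("Q%d", 1:20)), 0.0)
  expect_error(recall(character(), A), "non-empty")
})

test_that("discrimination counts strictly correct associations out of 2M", {
  d <- discrimination("P1", "P2", list("P1"), list("P2"))
  expect_equal(d$s, 1.0)
  expect_equal(d$total, 2L)

  # identical full-dataset lists: every comparison ties, s = 0
  A <- sprintf("P%d", 1:5)
  d <- discrimination(A, A, list(A, A), list(A, A))
  expect_equal(d$s, 0.0)

  # M = 2, 3 of 4 correct: the second a mis-associates (recalls 0 vs 1),
  # both a-primes associate correctly (1 vs 0 and 0.5 vs 0)
  d <- discrimination(
    c("P1", "P2"), c("Q1", "Q2"),
    list(c("P1", "P2"), c("Q1", "Q2")),
    list(c("Q1", "Q2"), c("Q1", "R1"))
  )
  expect_equal(d$correct, 3L)
  expect_equal(d$s, 0.75)

  expect_error(discrimination("P1", "P2", list("P1"), list()), "same number")
})

test_that("discrimination is symmetric in the two conditions", {
  withr::with_seed(19, {
    ids <- sprintf("P%d", 1:10)
    for (rep in 1:10) {
      A <- sample(ids, 3)
      Ap <- sample(ids, 3)
      al <- replicate(4, sample(ids, 3), simplify = FALSE)
      alp <- replicate(4, sample(ids, 3), simplify = FALSE)
      expect_equal(
        discrimination(A, Ap, al, alp)$s,
        discrimination(Ap, A, alp, al)$s
      )
    }
  })
})

test_that("generalized discrimination handles >2 datasets and reduces to the pairwise case", {
  A1 <- sprintf("A%d", 1:3)
  A2 <- sprintf("B%d", 1:3)
  A3 <- sprintf("C%d", 1:3)
  entries <- list(
    list(A = A1, a_list = list(A1[1:2])),
    list(A = A2, a_list = list(A2[1:2])),
    list(A = A3, a_list = list(A3[1:2]))
  )
  expect_equal(generalized_discrimination(entries)$s, 1.0)

  same <- list(
    list(A = A1, a_list = list(A1[1:2])),
    list(A = A1, a_list = list(A1[1:2]))
  )
  expect_equal(generalized_discrimination(same)$s, 0.0)

  withr::with_seed(23, {
    ids <- sprintf("P%d", 1:8)
    A <- sample(ids, 3)
    Ap <- sample(ids, 3)
    al <- replicate(5, sample(ids, 3), simplify = FALSE)
    alp <- replicate(5, sample(ids, 3), simplify = FALSE)
    expect_equal(
      generalized_discrimination(list(
        list(A = A, a_list = al), list(A = Ap, a_list = alp)
      ))$s,
      discrimination(A, Ap, al, alp)$s
    )
  })
  expect_error(generalized_discrimination(entries[1]), "At least 2")
})

test_that("a random stub's expected recall is K/P", {
  P <- 100
  K <- 20
  ids <- sprintf("P%d", seq_len(P))
  A <- ids[1:K]
  withr::with_seed(37, {
    r <- replicate(10000, recall(A, sample(ids, K)))
  })
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - K / P), 3 * se)
})

test_that("random-stub discrimination matches the exhaustively enumerated expectation", {
  # P = 4, K = 1, A = {P1}, A' = {P2}; a, a' uniform over singletons.
  # By enumeration: an a is correctly associated only when a = A
  # (recall 1 > 0); ties (recall 0 = 0) are incorrect. E[s] = 1/4.
  ids <- sprintf("P%d", 1:4)
  outcomes <- expand.grid(a = ids, ap = ids, stringsAsFactors = FALSE)
  s_exact <- mean(apply(outcomes, 1, function(row) {
    discrimination("P1", "P2", list(row[["a"]]), list(row[["ap"]]))$s
  }))
  expect_equal(s_exact, 0.25)

  withr::with_seed(41, {
    s_mc <- replicate(2000, {
      discrimination("P1", "P2", list(sample(ids, 1)), list(sample(ids, 1)))$s
    })
  })
  se <- sd(s_mc) / sqrt(length(s_mc))
  expect_lt(abs(mean(s_mc) - s_exact), 3 * se)
})

test_that("a constant-output ranker yields recall 1 everywhere", {
  coll <- block_collection(n_sets = 10, set_size = 5)
  D <- generate_dataset(
    synthetic_design(n_genes = 60, n_treatment = 10, n_control = 10, seed = 2, id = "cc"),
    coll
  )
  fixed <- random_ranking(coll$set_id, K = 3, seed = 99)
  stub <- function(D, coll, K, seed) fixed
  rr <- run_recall_experiment(D, coll, stub, sizes = c(6, 8), M = 4, K = 3, master_seed = 5)
  expect_true(all(rr$recall == 1))
  expect_equal(nrow(rr), 2 * 2 * 4) # sizes x directions x M
})

test_that("M = 0 gives an empty result without error", {
  coll <- block_collection(n_sets = 5, set_size = 4)
  D <- generate_dataset(
    synthetic_design(n_genes = 20, n_treatment = 8, n_control = 8, seed = 3, id = "m0"),
    coll
  )
  rr <- run_recall_experiment(
    D, coll, method_config("afc", B = 20),
    sizes = 6, M = 0, K = 2, master_seed = 1
  )
  expect_equal(nrow(rr), 0)
})

test_that("identical datasets give zero discrimination; same-seed pair is identical", {
  coll <- block_collection(n_sets = 10, set_size = 5)
  design <- synthetic_design(
    n_genes = 60, n_treatment = 12, n_control = 12,
    perturbed = list(S01 = list(delta = 2)), seed = 4, id = "twin"
  )
  pair <- generate_benchmark_pair(design, design, coll)
  expect_identical(pair[[1]]$values, pair[[2]]$values)
  dr <- run_discrimination_experiment(
    pair[[1]], pair[[2]], coll, method_config("afc", B = 50),
    sizes = 8, M = 3, K = 3, master_seed = 6
  )
  expect_true(all(dr$s == 0))
  expect_true(all(dr$total == 6))
})

test_that("cross-dataset overlap is 1 for the same dataset and 0 for disjoint stubs", {
  coll <- block_collection(n_sets = 10, set_size = 5)
  D <- generate_dataset(
    synthetic_design(n_genes = 60, n_treatment = 10, n_control = 10, seed = 8, id = "ov"),
    coll
  )
  out <- cross_dataset_overlap(D, D, coll, method_config("afc", B = 30), K = 4)
  expect_equal(out$overlap, c(1, 1))

  stub_small <- function(D, coll, K, seed) random_ranking(coll$set_id[1:4], K, seed = 1)
  stub_large <- function(D, coll, K, seed) random_ranking(coll$set_id[5:8], K, seed = 2)
  # two fixed stubs with disjoint outputs
  A_small <- stub_small(D, coll, 4, 1)
  A_large <- stub_large(D, coll, 4, 1)
  expect_equal(recall(ranking_ids(A_large, "up"), ranking_ids(A_small, "up")), 0)
})

test_that("sample-label methods skip sizes that leave cohorts under 3", {
  coll <- block_collection(n_sets = 5, set_size = 4)
  D <- generate_dataset(
    synthetic_design(n_genes = 20, n_treatment = 10, n_control = 10, seed = 5, id = "sk"),
    coll
  )
  # n = 4 leaves 2 per cohort (< 3): skipped; n = 6 (3 per cohort) is kept
  expect_warning(
    rr <- run_recall_experiment(
      D, coll, method_config("afcs", B = 20),
      sizes = c(4, 6), M = 2, K = 2, master_seed = 2
    ),
    "Skipping size"
  )
  expect_equal(sort(unique(rr$n)), 6L)
})
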