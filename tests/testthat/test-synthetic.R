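test_that("generation is a deterministic function of the design", {
  coll <- block_collection(n_sets = 10, set_size = 5)
  design <- synthetic_design(
    n_genes = 80, n_treatment = 6, n_control = 6,
    perturbed = list(S02 = list(delta = 1.5, direction = "down")),
    rho = 0.3, seed = 42, id = "det"
  )
  D1 <- generate_dataset(design, coll)
  D2 <- generate_dataset(design, coll)
  expect_identical(D1$values, D2$values)
  design$seed <- 43L
  D3 <- generate_dataset(design, coll)
  expect_false(identical(D1$values, D3$values))
})

test_that("unknown perturbed set ids and undersized universes are rejected", {
  coll <- block_collection(n_sets = 4, set_size = 5)
  expect_error(
    generate_dataset(
      synthetic_design(n_genes = 30, perturbed = list(NOPE = list(delta = 1))),
      coll
    ),
    "NOPE"
  )
  expect_error(
    generate_dataset(synthetic_design(n_genes = 10), coll),
    "universe"
  )
  expect_error(synthetic_design(rho = 1), "rho")
  expect_error(synthetic_design(sigma = 0), "sigma")
})

test_that("injected shifts are recovered by the estimated fold changes", {
  coll <- block_collection(n_sets = 20, set_size = 20)
  design <- synthetic_design(
    n_genes = 500, n_treatment = 100, n_control = 100,
    perturbed = list(S01 = list(delta = 2, fraction = 1, direction = "up")),
    sigma = 1, seed = 7, id = "rec"
  )
  D <- generate_dataset(design, coll)
  stats <- compute_gene_stats(D)
  affected <- stats$fold_change[match(coll$genes[[1]], stats$gene_id)]
  # each gene's fold-change estimate has variance sigma^2 * (1/100 + 1/100)
  se <- sqrt(0.02 / length(affected))
  expect_lt(abs(mean(affected) - 2), 3 * se)
  background <- stats$fold_change[match(coll$genes[[5]], stats$gene_id)]
  expect_lt(abs(mean(background)), 3 * se)
})

test_that("fold-change regression on injected shift has slope near 1", {
  coll <- block_collection(n_sets = 10, set_size = 20)
  deltas <- c(S01 = 0.5, S02 = 1, S03 = 1.5, S04 = 2)
  design <- synthetic_design(
    n_genes = 200, n_treatment = 150, n_control = 150,
    perturbed = lapply(as.list(deltas), function(d) list(delta = d)),
    seed = 11, id = "slope"
  )
  D <- generate_dataset(design, coll)
  stats <- compute_gene_stats(D)
  truth <- rep(0, nrow(stats))
  for (sid in names(deltas)) {
    truth[match(coll$genes[[which(coll$set_id == sid)]], stats$gene_id)] <- deltas[[sid]]
  }
  fit <- stats::lm(stats$fold_change ~ truth)
  ci <- stats::confint(fit)["truth", ]
  expect_gt(1, ci[1])
  expect_lt(1, ci[2])
})

test_that("direction and fraction control which member genes shift", {
  coll <- block_collection(n_sets = 4, set_size = 20)
  design <- synthetic_design(
    n_genes = 80, n_treatment = 200, n_control = 200,
    perturbed = list(
      S01 = list(delta = 3, direction = "down"),
      S02 = list(delta = 3, fraction = 0.5),
      S03 = list(delta = 3, direction = "mixed")
    ),
    seed = 13, id = "dirs"
  )
  D <- generate_dataset(design, coll)
  fc <- compute_gene_stats(D)$fold_change
  names(fc) <- rownames(D$values)
  expect_true(all(fc[coll$genes[[1]]] < -1))
  shifted <- sum(fc[coll$genes[[2]]] > 1.5)
  expect_equal(shifted, 10)
  mixed <- fc[coll$genes[[3]]]
  expect_equal(sum(mixed > 1.5), 10)
  expect_equal(sum(mixed < -1.5), 10)
})

test_that("within-set correlation tracks rho and vanishes at rho = 0", {
  coll <- block_collection(n_sets = 10, set_size = 20)
  base <- list(
    n_genes = 250, n_treatment = 100, n_control = 100, seed = 17
  )
  D0 <- generate_dataset(do.call(synthetic_design, c(base, list(rho = 0, id = "r0"))), coll)
  D3 <- generate_dataset(do.call(synthetic_design, c(base, list(rho = 0.3, id = "r3"))), coll)
  within_cor <- function(D) {
    cc <- cor(t(D$values[coll$genes[[1]], ]))
    mean(cc[upper.tri(cc)])
  }
  expect_lt(abs(within_cor(D0)), 0.05)
  expect_lt(abs(within_cor(D3) - 0.3), 0.08)
  # genes from different sets stay uncorrelated
  cross <- cor(
    t(D3$values[coll$genes[[1]][1:10], ]),
    t(D3$values[coll$genes[[2]][1:10], ])
  )
  expect_lt(abs(mean(cross)), 0.05)
})

test_that("benchmark pairs share the gene universe and differ across seeds", {
  coll <- block_collection(n_sets = 6, set_size = 5)
  dA <- synthetic_design(
    n_genes = 40, n_treatment = 8, n_control = 8,
    perturbed = list(S01 = list(delta = 2)), seed = 1, id = "pairA"
  )
  dB <- synthetic_design(
    n_genes = 40, n_treatment = 8, n_control = 8,
    perturbed = list(S04 = list(delta = 2)), seed = 2, id = "pairB"
  )
  pair <- generate_benchmark_pair(dA, dB, coll)
  expect_equal(rownames(pair[[1]]$values), rownames(pair[[2]]$values))
  expect_false(identical(pair[[1]]$values, pair[[2]]$values))
  dB$n_genes <- 50L
  expect_error(generate_benchmark_pair(dA, dB, coll), "n_genes")
})
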