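# Permutation null distributions for AFC, GSEA and GSA pathway scores:
# gene-label permutation, sample-label permutation (with exact enumeration
# when feasible) and GSA's restandardization combining the two axes.

#' Permutation p-values for pathway scores
#'
#' Scores every pathway on the observed data and against a permutation
#' null, returning one-sided p-values in both directions with the add-one
#' estimator `p_up = (#\{null >= observed\} + 1) / (B_eff + 1)` (and `<=`
#' for `p_down`), which can never be exactly zero.
#'
#' Null modes:
#' * `gene_label`: each replicate permutes the assignment of per-gene
#'   statistics to gene identities (one shared permutation per replicate)
#'   and rescores all pathways.
#' * `sample_label`: each replicate reassigns cohort labels over samples,
#'   preserving cohort sizes, recomputes the per-gene statistics and
#'   rescores. When the number of distinct assignments (complementary
#'   assignments identified for equal cohorts) is at most `cfg$B`, all of
#'   them are enumerated exactly and `B_eff` equals that count; a 3-vs-3
#'   dataset has exactly 10.
#' * `restandardization` (GSA): sample-label permutation in which both the
#'   observed and each permuted maxmean score are centered and scaled by
#'   the gene-randomization (random gene set) moments of the corresponding
#'   data, estimated by Monte-Carlo over `cfg$gsa_random_sets` random sets
#'   per set size with an index design shared across permutations.
#'
#' @param D An [expression_dataset()].
#' @param coll A [geneset_collection()] restricted to the measured genes.
#' @param scorer `"afc"`, `"gsea"` or `"gsa"`.
#' @param cfg A [method_config()]; its `permutation_mode`, `B` and `seed`
#'   drive the null.
#' @return A tibble with columns `set_id`, `score` (observed signed score;
#'   restandardized for GSA), `p_up`, `p_down`, plus attribute `B_eff`.
#' @export
permutation_pvalues <- function(D, coll, scorer = c("afc", "gsea", "gsa"), cfg) {
  scorer <- match.arg(scorer)
  mode <- cfg$permutation_mode
  if (mode == "none") abort("`cfg$permutation_mode` must specify a null.")
  X <- D$values
  idx_list <- lapply(coll$genes, match, rownames(X))
  if (any(vapply(idx_list, anyNA, logical(1)))) {
    abort("Collection must be restricted to measured genes first.")
  }
  stats <- compute_gene_stats(D, welch = cfg$welch)

  if (mode == "gene_label") {
    res <- null_gene_label(stats, idx_list, scorer, cfg, nrow(X))
  } else {
    labels <- permutation_labels(D, cfg)
    if (min(colSums(labels)) < 2L || min(colSums(!labels)) < 2L) {
      abort("Sample-label permutation requires at least 2 samples per permuted cohort.")
    }
    res <- if (mode == "restandardization") {
      null_restandardized(X, stats, labels, idx_list, cfg)
    } else {
      null_sample_label(X, stats, labels, idx_list, scorer, cfg)
    }
  }
  obs <- res$obs
  nulls <- res$nulls # sets x B_eff
  B_eff <- ncol(nulls)
  # tolerance so exact ties (e.g. the observed assignment among enumerated
  # nulls) are counted despite differing floating-point evaluation routes
  tol <- 1e-9 * pmax(abs(obs), 1)
  out <- tibble(
    set_id = coll$set_id,
    score = obs,
    p_up = (rowSums(nulls >= obs - tol) + 1) / (B_eff + 1),
    p_down = (rowSums(nulls <= obs + tol) + 1) / (B_eff + 1)
  )
  attr(out, "B_eff") <- B_eff
  out
}

# ---- per-gene statistic feeding each scorer ---------------------------------

scorer_stat <- function(stats, scorer, cfg) {
  switch(scorer,
    afc = stats$fold_change,
    gsa = stats$t,
    gsea = if (cfg$rank_by == "t") stats$t else stats$fold_change
  )
}

# scores of all sets for one per-gene statistic vector
score_sets <- function(z, idx_list, scorer, cfg) {
  switch(scorer,
    afc = vapply(idx_list, function(i) mean(z[i]), numeric(1)),
    gsa = vapply(idx_list, function(i) maxmean_from_z(z[i]), numeric(1)),
    gsea = gsea_scores_from_stat(z, idx_list, cfg$gsea_weight)
  )
}

gsea_scores_from_stat <- function(z, idx_list, p) {
  G <- length(z)
  ord <- order(-z)
  position <- integer(G)
  position[ord] <- seq_len(G)
  w_sorted <- abs(z[ord])^p
  vapply(idx_list, function(i) {
    pos <- sort(position[i])
    es_from_positions(pos, w_sorted[pos], G)
  }, numeric(1))
}

# membership weight matrix: sets x genes, entries 1/|set| at member genes,
# so Mm %*% z gives the per-set mean of z
membership_matrix <- function(idx_list, G) {
  S <- length(idx_list)
  Mm <- matrix(0, S, G)
  for (s in seq_len(S)) Mm[s, idx_list[[s]]] <- 1 / length(idx_list[[s]])
  Mm
}

# per-set maxmean for every column of a genes x B statistic matrix
maxmean_matrix <- function(Mm, Z) {
  SP <- Mm %*% pmax(Z, 0)
  SN <- Mm %*% pmax(-Z, 0)
  ifelse(SP > SN, SP, -SN)
}

# ---- gene-label null --------------------------------------------------------

null_gene_label <- function(stats, idx_list, scorer, cfg, G) {
  z <- scorer_stat(stats, scorer, cfg)
  obs <- score_sets(z, idx_list, scorer, cfg)
  nulls <- withr::with_seed(derive_seed(cfg$seed, "gene_label", scorer), {
    if (scorer == "gsea") {
      m <- vapply(seq_len(cfg$B), function(b) {
        rp <- sample.int(G)
        score_sets(z, lapply(idx_list, function(i) rp[i]), scorer, cfg)
      }, numeric(length(idx_list)))
      matrix(m, nrow = length(idx_list))
    } else {
      # one shared gene permutation per replicate, all sets rescored at once
      P <- vapply(seq_len(cfg$B), function(b) sample.int(G), integer(G))
      Zp <- matrix(z[P], G, cfg$B)
      Mm <- membership_matrix(idx_list, G)
      if (scorer == "afc") Mm %*% Zp else maxmean_matrix(Mm, Zp)
    }
  })
  list(obs = obs, nulls = nulls)
}

# ---- sample-label machinery -------------------------------------------------

# Logical matrix (samples x B_eff), TRUE = treatment; exact enumeration when
# the distinct-assignment count is within budget, else B sampled assignments.
permutation_labels <- function(D, cfg) {
  N <- ncol(D$values)
  n1 <- sum(D$cohort == "treatment")
  n_distinct <- count_distinct_label_assignments(n1, N - n1)
  if (n_distinct <= cfg$B) {
    return(enumerate_label_assignments(n1, N - n1))
  }
  withr::with_seed(derive_seed(cfg$seed, "sample_label", D$id), {
    vapply(seq_len(cfg$B), function(b) {
      lab <- rep(FALSE, N)
      lab[sample.int(N, n1)] <- TRUE
      lab
    }, logical(N))
  })
}

null_sample_label <- function(X, stats, labels, idx_list, scorer, cfg) {
  z_obs <- scorer_stat(stats, scorer, cfg)
  obs <- score_sets(z_obs, idx_list, scorer, cfg)
  perm <- batch_gene_stats(X, labels, welch = cfg$welch)
  Z <- switch(scorer,
    afc = perm$fold_change,
    gsa = perm$t,
    gsea = if (cfg$rank_by == "t") perm$t else perm$fold_change
  )
  Mm <- if (scorer != "gsea") membership_matrix(idx_list, nrow(X))
  nulls <- switch(scorer,
    afc = Mm %*% Z,
    gsa = maxmean_matrix(Mm, Z),
    gsea = matrix(
      vapply(
        seq_len(ncol(Z)),
        function(b) score_sets(Z[, b], idx_list, scorer, cfg),
        numeric(length(idx_list))
      ),
      nrow = length(idx_list)
    )
  )
  list(obs = obs, nulls = nulls)
}

# ---- GSA restandardization --------------------------------------------------

# Aggregation matrices for the gene-randomization moments: for each unique
# set size m, an R x G matrix averaging over R pre-drawn random gene sets of
# size m (the same random design is reused for the observed data and every
# sample permutation).
randomization_designs <- function(sizes, G, R, seed) {
  withr::with_seed(seed, {
    lapply(setNames(nm = sort(unique(sizes))), function(m) {
      A <- matrix(0, R, G)
      for (r in seq_len(R)) A[r, sample.int(G, m)] <- 1 / m
      A
    })
  })
}

# mean/sd of the maxmean statistic over random gene sets, per size and per
# column of the genes x B statistic matrix Z
randomization_moments <- function(Z, designs) {
  Zp <- pmax(Z, 0)
  Zn <- pmax(-Z, 0)
  lapply(designs, function(A) {
    SP <- A %*% Zp
    SN <- A %*% Zn
    MM <- ifelse(SP > SN, SP, -SN)
    R <- nrow(MM)
    mu <- colMeans(MM)
    sg <- sqrt(pmax(colSums(MM^2) / R - mu^2, 0) * R / (R - 1))
    sg[sg == 0 | is.na(sg)] <- 1
    list(mean = mu, sd = sg)
  })
}

null_restandardized <- function(X, stats, labels, idx_list, cfg) {
  sizes <- lengths(idx_list)
  G <- nrow(X)
  designs <- randomization_designs(
    sizes, G, cfg$gsa_random_sets,
    derive_seed(cfg$seed, "gsa_random_sets")
  )
  Mm <- membership_matrix(idx_list, G)
  key <- as.character(sizes)
  standardize <- function(Z) {
    raw <- maxmean_matrix(Mm, Z) # sets x B
    mom <- randomization_moments(Z, designs)
    mu <- do.call(rbind, lapply(mom, `[[`, "mean"))[key, , drop = FALSE]
    sg <- do.call(rbind, lapply(mom, `[[`, "sd"))[key, , drop = FALSE]
    (raw - mu) / sg
  }
  obs <- drop(standardize(matrix(stats$t, ncol = 1)))
  perm <- batch_gene_stats(X, labels, welch = cfg$welch)
  nulls <- standardize(perm$t)
  list(obs = obs, nulls = nulls)
}
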