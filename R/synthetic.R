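# Synthetic two-cohort expression data with controlled pathway-level
# perturbation: the ground-truth test bed for every method and metric.

#' Build a block gene-set collection
#'
#' Assigns `n_sets * set_size` synthetic gene symbols to consecutive,
#' mutually disjoint gene sets — the default layout of the synthetic
#' benchmark (100 sets of 20 genes over 2000 genes).
#'
#' @param n_sets Number of gene sets.
#' @param set_size Genes per set.
#' @param gene_prefix,set_prefix Symbol prefixes.
#' @return A [geneset_collection()].
#' @export
block_collection <- function(n_sets = 100, set_size = 20,
                             gene_prefix = "g", set_prefix = "S") {
  genes <- sprintf("%s%05d", gene_prefix, seq_len(n_sets * set_size))
  geneset_collection(
    set_id = sprintf("%s%02d", set_prefix, seq_len(n_sets)),
    name = "synthetic block set",
    genes = split(genes, rep(seq_len(n_sets), each = set_size))
  )
}

#' Parameterize a synthetic two-cohort expression dataset
#'
#' The generative model: log2 expression of gene g in sample j is
#' `mu + sqrt(rho) * U_{s(g),j} + sqrt(1 - rho) * E_{g,j}`, with `U` a
#' per-set, per-sample shared factor and `E` independent noise, both
#' standard Gaussian scaled by `sigma`; genes within a set are therefore
#' equicorrelated with correlation `rho`. For each perturbed set, a fraction
#' `f` of its member genes (a seeded draw) additionally receives an additive
#' shift of `+delta` (`direction = "up"`), `-delta` (`"down"`) or half each
#' (`"mixed"`) in the treatment samples only; genes in several perturbed
#' sets accumulate the sum of their shifts.
#'
#' @param n_genes Total measured genes (must cover the collection universe).
#' @param n_treatment,n_control Cohort sizes.
#' @param perturbed Named list keyed by gene-set id; each element a list with
#'   `delta` (log2 shift), `fraction` (affected fraction of member genes,
#'   default 1) and `direction` (`"up"`, `"down"` or `"mixed"`, default
#'   `"up"`).
#' @param mu,sigma Baseline mean and standard deviation of log2 expression.
#' @param rho Within-set equicorrelation, `0 <= rho < 1`.
#' @param seed Seed; the dataset is a deterministic function of the design.
#' @param id Dataset identifier.
#' @return A `synthetic_design` list.
#' @export
synthetic_design <- function(n_genes = 2000, n_treatment = 60, n_control = 60,
                             perturbed = list(), mu = 7, sigma = 1, rho = 0,
                             seed = 1L, id = "synthetic") {
  check_scalar_int(n_genes, "n_genes", min = 1)
  check_scalar_int(n_treatment, "n_treatment", min = 2)
  check_scalar_int(n_control, "n_control", min = 2)
  if (!is.numeric(sigma) || sigma <= 0) abort("`sigma` must be > 0.")
  if (!is.numeric(rho) || rho < 0 || rho >= 1) abort("`rho` must lie in [0, 1).")
  perturbed <- lapply(perturbed, function(p) {
    p <- utils::modifyList(list(delta = 1, fraction = 1, direction = "up"), p)
    if (!is.finite(p$delta)) abort("`delta` must be finite.")
    if (p$fraction <= 0 || p$fraction > 1) abort("`fraction` must lie in (0, 1].")
    if (!p$direction %in% c("up", "down", "mixed")) {
      abort("`direction` must be 'up', 'down' or 'mixed'.")
    }
    p
  })
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_treatment = as.integer(n_treatment),
      n_control = as.integer(n_control),
      perturbed = perturbed, mu = mu, sigma = sigma, rho = rho,
      seed = as.integer(seed), id = id
    ),
    class = "synthetic_design"
  )
}

#' Generate a synthetic two-cohort expression dataset
#'
#' Draws a dataset from the model of [synthetic_design()]. Genes of the
#' collection's universe occupy the first rows; extra genes up to `n_genes`
#' are pure background named `bg...`. A gene belonging to several sets takes
#' its shared correlated component from the first containing set.
#'
#' @param design A [synthetic_design()].
#' @param coll A [geneset_collection()] whose universe fits in
#'   `design$n_genes`; all perturbed set ids must exist in it.
#' @return An [expression_dataset()].
#' @export
generate_dataset <- function(design, coll) {
  unknown <- setdiff(names(design$perturbed), coll$set_id)
  if (length(unknown)) {
    abort(sprintf("Unknown perturbed set id(s): %s", paste(unknown, collapse = ", ")))
  }
  universe <- gene_universe(coll)
  if (length(universe) > design$n_genes) {
    abort("`n_genes` must cover the collection's gene universe.")
  }
  gene_ids <- c(
    universe,
    sprintf("bg%05d", seq_len(design$n_genes - length(universe)))
  )
  G <- design$n_genes
  N <- design$n_treatment + design$n_control
  # first containing set per gene (0 = none) drives the shared component
  set_of_gene <- rep(0L, G)
  for (s in rev(seq_len(nrow(coll)))) {
    set_of_gene[match(coll$genes[[s]], gene_ids)] <- s
  }
  withr::with_seed(derive_seed(design$seed, design$id, "generate"), {
    E <- matrix(rnorm(G * N), G, N)
    X <- design$mu + design$sigma * sqrt(1 - design$rho) * E
    if (design$rho > 0 && any(set_of_gene > 0)) {
      U <- matrix(rnorm(nrow(coll) * N), nrow(coll), N)
      shared <- set_of_gene > 0
      X[shared, ] <- X[shared, ] +
        design$sigma * sqrt(design$rho) * U[set_of_gene[shared], ]
    }
    shift <- rep(0, G)
    for (sid in names(design$perturbed)) {
      p <- design$perturbed[[sid]]
      members <- match(coll$genes[[which(coll$set_id == sid)]], gene_ids)
      k <- max(1L, round(p$fraction * length(members)))
      affected <- if (k < length(members)) sort(sample(members, k)) else members
      delta <- switch(p$direction,
        up = rep(p$delta, k),
        down = rep(-p$delta, k),
        mixed = rep_len(c(p$delta, -p$delta), k)
      )
      shift[affected] <- shift[affected] + delta
    }
    X[, seq_len(design$n_treatment)] <- X[, seq_len(design$n_treatment)] + shift
  })
  colnames(X) <- sprintf("%s_s%03d", design$id, seq_len(N))
  rownames(X) <- gene_ids
  expression_dataset(
    X,
    rep(c("treatment", "control"), c(design$n_treatment, design$n_control)),
    id = design$id
  )
}

#' Generate a pair of synthetic datasets sharing one gene universe
#'
#' Two independent datasets from two designs over the same collection —
#' the synthetic analogue of two studies of different conditions used by
#' the discrimination experiment. Typically the designs perturb disjoint
#' (or partially overlapping) groups of gene sets.
#'
#' @param design_a,design_b Two [synthetic_design()]s with equal `n_genes`.
#' @param coll The shared [geneset_collection()].
#' @return A list of two [expression_dataset()]s.
#' @export
generate_benchmark_pair <- function(design_a, design_b, coll) {
  if (design_a$n_genes != design_b$n_genes) {
    abort("Both designs must specify the same `n_genes`.")
  }
  list(
    generate_dataset(design_a, coll),
    generate_dataset(design_b, coll)
  )
}
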