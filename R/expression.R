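# Two-cohort expression datasets: container, TSV/CLS readers, stratified
# subsampling, and the combinatorics of distinct sample-label assignments.

#' Construct a two-cohort expression dataset
#'
#' Holds a genes x samples matrix of log2-scale expression values together
#' with a treatment/control cohort assignment. Both an original dataset `D`
#' (N samples) and any resampled sub-dataset `d` (n < N samples) use this
#' container.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene symbols) and colnames (sample ids). No missing
#'   values allowed.
#' @param cohort Character vector (length = ncol(values)) of labels
#'   `"treatment"` / `"control"`, or a named vector keyed by sample id.
#' @param id Optional dataset identifier (used in seed derivation and
#'   result tables).
#' @return An `expression_dataset`.
#' @export
expression_dataset <- function(values, cohort, id = "dataset") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    abort(sprintf(
      "Duplicate gene id(s): %s",
      paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", ")
    ))
  }
  if (anyDuplicated(colnames(values))) abort("Duplicate sample ids.")
  if (anyNA(values)) abort("`values` must not contain missing values.")
  if (!is.null(names(cohort))) {
    missing <- setdiff(colnames(values), names(cohort))
    if (length(missing)) {
      abort(sprintf(
        "Sample(s) missing from the phenotype assignment: %s",
        paste(missing, collapse = ", ")
      ))
    }
    cohort <- cohort[colnames(values)]
  }
  cohort <- as.character(cohort)
  if (length(cohort) != ncol(values)) {
    abort("`cohort` must assign every sample a label.")
  }
  bad <- setdiff(unique(cohort), c("treatment", "control"))
  if (length(bad)) {
    abort(sprintf(
      "Unknown cohort label(s): %s (expected 'treatment'/'control')",
      paste(bad, collapse = ", ")
    ))
  }
  if (sum(cohort == "treatment") < 2L || sum(cohort == "control") < 2L) {
    abort("Each cohort must contain at least 2 samples.")
  }
  structure(
    list(values = values, cohort = setNames(cohort, colnames(values)), id = id),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> '%s': %d genes x %d samples (%d treatment, %d control)\n",
    x$id, nrow(x$values), ncol(x$values),
    sum(x$cohort == "treatment"), sum(x$cohort == "control")
  ))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Sample ids of one cohort
#' @param D An [expression_dataset()].
#' @param cohort `"treatment"` or `"control"`.
#' @return Character vector of sample ids.
#' @export
cohort_samples <- function(D, cohort = c("treatment", "control")) {
  cohort <- match.arg(cohort)
  names(D$cohort)[D$cohort == cohort]
}

#' Read a two-cohort expression dataset from disk
#'
#' The expression matrix is a tab-delimited file whose header row carries
#' sample ids and whose first column carries gene symbols; values are
#' log2-scale (already normalized). The phenotype file is either GSEA CLS
#' (three header-ish lines, labels on the third) or a two-column TSV
#' (sample_id, label). Labels other than `treatment`/`control` are accepted
#' in CLS files: the first class name is mapped to treatment, the second to
#' control.
#'
#' @param matrix_path Path to the expression TSV.
#' @param phenotype_path Path to the phenotype CLS or TSV file.
#' @param id Dataset identifier (defaults to the matrix file name).
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, phenotype_path,
                            id = tools::file_path_sans_ext(basename(matrix_path))) {
  if (!file.exists(matrix_path)) abort(sprintf("Matrix file not found: %s", matrix_path))
  if (!file.exists(phenotype_path)) abort(sprintf("Phenotype file not found: %s", phenotype_path))
  tab <- readr::read_tsv(matrix_path, show_col_types = FALSE, progress = FALSE)
  genes <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  cohort <- read_phenotype(phenotype_path, colnames(values))
  expression_dataset(values, cohort, id = id)
}

# Phenotype reader: CLS dialect or two-column TSV. Returns a named vector of
# treatment/control labels covering `sample_ids`.
read_phenotype <- function(path, sample_ids) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) >= 3 && grepl("^\\d+\\s+\\d+\\s+1\\s*$", lines[1])) {
    # CLS: "<n> <k> 1" / "# class1 class2" / labels
    classes <- strsplit(sub("^#\\s*", "", lines[2]), "\\s+")[[1]]
    labels <- strsplit(trimws(lines[3]), "\\s+")[[1]]
    if (length(labels) != length(sample_ids)) {
      abort(sprintf(
        "CLS file assigns %d labels but the matrix has %d samples.",
        length(labels), length(sample_ids)
      ))
    }
    # numeric CLS labels index the class names; string labels are used directly
    if (all(labels %in% as.character(seq_along(classes) - 1))) {
      labels <- classes[as.integer(labels) + 1L]
    }
    map <- setNames(c("treatment", "control"), classes[1:2])
    unknown <- setdiff(unique(labels), names(map))
    if (length(unknown)) {
      abort(sprintf("Unknown CLS label(s): %s", paste(unknown, collapse = ", ")))
    }
    return(setNames(unname(map[labels]), sample_ids))
  }
  tab <- readr::read_tsv(
    path,
    col_names = c("sample_id", "label"),
    show_col_types = FALSE, progress = FALSE
  )
  # tolerate a header row
  if (identical(tolower(tab$sample_id[1]), "sample_id")) tab <- tab[-1, ]
  missing <- setdiff(sample_ids, tab$sample_id)
  if (length(missing)) {
    abort(sprintf(
      "Sample(s) missing from the phenotype file: %s",
      paste(missing, collapse = ", ")
    ))
  }
  setNames(tolower(tab$label), tab$sample_id)[sample_ids]
}

#' Write an expression dataset to TSV + CLS files
#'
#' @param D An [expression_dataset()].
#' @param matrix_path,phenotype_path Output paths (TSV matrix, CLS labels).
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(D, matrix_path, phenotype_path) {
  tab <- tibble::as_tibble(D$values, rownames = "gene_id")
  readr::write_tsv(tab, matrix_path, progress = FALSE)
  writeLines(
    c(
      sprintf("%d 2 1", ncol(D$values)),
      "# treatment control",
      paste(D$cohort, collapse = " ")
    ),
    phenotype_path
  )
  invisible(matrix_path)
}

#' Specify one stratified sub-dataset draw
#'
#' @param n_treatment,n_control Number of samples to draw (without
#'   replacement) from each cohort; each must be >= 2.
#' @param seed Master seed of the experiment.
#' @param replicate_index Replicate number `i`; together with `seed` it
#'   determines the draw.
#' @return A `subsample_spec` list with element `n = n_treatment + n_control`.
#' @export
subsample_spec <- function(n_treatment, n_control, seed = 1L, replicate_index = 1L) {
  check_scalar_int(n_treatment, "n_treatment", min = 2)
  check_scalar_int(n_control, "n_control", min = 2)
  check_scalar_int(replicate_index, "replicate_index", min = 0)
  structure(
    list(
      n = as.integer(n_treatment + n_control),
      n_treatment = as.integer(n_treatment),
      n_control = as.integer(n_control),
      seed = as.integer(seed),
      replicate_index = as.integer(replicate_index)
    ),
    class = "subsample_spec"
  )
}

#' Split a sub-dataset size between the cohorts
#'
#' `"stratified"` takes n/2 from each cohort (n must be even);
#' `"proportional"` allocates proportionally to the parent cohort sizes
#' (rounded, at least 2 per cohort).
#'
#' @param n Total sub-dataset size.
#' @param n1,n2 Parent treatment/control cohort sizes.
#' @param allocation `"stratified"` or `"proportional"`.
#' @return Integer vector `c(n_treatment, n_control)`.
#' @export
allocate_cohorts <- function(n, n1, n2, allocation = c("stratified", "proportional")) {
  allocation <- match.arg(allocation)
  check_scalar_int(n, "n", min = 4)
  if (allocation == "stratified") {
    if (n %% 2 != 0) abort("Stratified allocation requires an even sub-dataset size.")
    return(c(n %/% 2L, n %/% 2L))
  }
  k1 <- max(2L, min(n - 2L, as.integer(round(n * n1 / (n1 + n2)))))
  c(k1, as.integer(n) - k1)
}

#' Draw a stratified random sub-dataset
#'
#' Selects `spec$n_treatment` treatment columns and `spec$n_control` control
#' columns uniformly at random without replacement. Values are column
#' selections of the parent matrix (never recomputed); cohort labels carry
#' over. The draw is a deterministic function of `spec$seed` and
#' `spec$replicate_index`.
#'
#' @param D An [expression_dataset()].
#' @param spec A [subsample_spec()].
#' @return An [expression_dataset()] with `spec$n` samples.
#' @export
subsample <- function(D, spec) {
  tr <- cohort_samples(D, "treatment")
  ct <- cohort_samples(D, "control")
  if (spec$n_treatment > length(tr)) {
    abort(sprintf(
      "Requested %d treatment samples but only %d available.",
      spec$n_treatment, length(tr)
    ))
  }
  if (spec$n_control > length(ct)) {
    abort(sprintf(
      "Requested %d control samples but only %d available.",
      spec$n_control, length(ct)
    ))
  }
  if (spec$n >= ncol(D$values)) {
    abort("Sub-dataset size must be smaller than the parent dataset.")
  }
  cols <- withr::with_seed(
    derive_seed(spec$seed, D$id, "subsample", spec$replicate_index),
    c(sample(tr, spec$n_treatment), sample(ct, spec$n_control))
  )
  expression_dataset(
    D$values[, cols, drop = FALSE],
    D$cohort[cols],
    id = sprintf("%s_n%d_r%d", D$id, spec$n, spec$replicate_index)
  )
}

#' Count distinct sample-label assignments
#'
#' The number of distinct ways of reassigning cohort labels to `n1 + n2`
#' samples while preserving cohort sizes. When the cohorts have equal size,
#' complementary assignments (treatment and control swapped wholesale) give
#' mirrored statistics and are identified, so the count is `C(n1+n2, n1) / 2`;
#' a 3-vs-3 dataset therefore has only 10 distinct assignments. For unequal
#' cohorts all `C(n1+n2, n1)` assignments are distinct.
#'
#' @param n1,n2 Cohort sizes (each >= 1).
#' @return Number of distinct assignments.
#' @export
count_distinct_label_assignments <- function(n1, n2) {
  check_scalar_int(n1, "n1", min = 1)
  check_scalar_int(n2, "n2", min = 1)
  total <- choose(n1 + n2, n1)
  if (n1 == n2) total / 2 else total
}

# All distinct label assignments as a logical matrix (N x n_assignments);
# TRUE marks a sample assigned to the treatment cohort. For equal cohort
# sizes only the representative of each complementary pair containing
# sample 1 is kept.
enumerate_label_assignments <- function(n1, n2) {
  N <- n1 + n2
  combos <- combn(N, n1)
  if (n1 == n2) combos <- combos[, combos[1, ] == 1L, drop = FALSE]
  out <- matrix(FALSE, N, ncol(combos))
  out[cbind(as.vector(combos), rep(seq_len(ncol(combos)), each = n1))] <- TRUE
  out
}
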