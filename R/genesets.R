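# Gene-set collections: GMT parsing, size filtering and restriction to the
# measured gene universe shared with an expression dataset.

#' Construct a gene-set collection
#'
#' A collection is a tibble with one row per gene set: `set_id` (unique
#' pathway identifier), `name` (free-text description) and `genes` (a
#' list-column of unique gene symbols). The gene universe of a collection is
#' always the union of its member sets (see [gene_universe()]).
#'
#' @param set_id Character vector of unique pathway identifiers.
#' @param name Character vector of descriptions (recycled if length 1).
#' @param genes List of character vectors of member gene symbols. Duplicate
#'   symbols within a set are collapsed; empty sets are an error. Gene
#'   identity is exact, case-sensitive string match.
#' @return A `geneset_collection`, a tibble subclass.
#' @examples
#' geneset_collection(c("P1", "P2"), "toy", list(c("g1", "g2"), c("g2", "g3")))
#' @export
geneset_collection <- function(set_id, name = "", genes = list()) {
  set_id <- as.character(set_id)
  if (anyDuplicated(set_id)) {
    abort(sprintf(
      "Duplicate gene-set id(s): %s",
      paste(unique(set_id[duplicated(set_id)]), collapse = ", ")
    ))
  }
  if (length(genes) != length(set_id)) {
    abort("`genes` must have one element per `set_id`.")
  }
  genes <- unname(lapply(genes, function(g) unique(as.character(g))))
  sizes <- lengths(genes)
  if (any(sizes == 0L) && length(sizes)) {
    abort(sprintf(
      "Gene set(s) with no member genes: %s",
      paste(set_id[sizes == 0L], collapse = ", ")
    ))
  }
  out <- tibble(
    set_id = set_id,
    name = rep_len(as.character(name), length(set_id)),
    genes = genes,
    size = sizes
  )
  class(out) <- c("geneset_collection", class(out))
  out
}

#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-delimited format distributed by MSigDB: one set per line,
#' fields are set id, description, then member gene symbols. Duplicate
#' symbols within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A [geneset_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(geneset_collection(character(), character(), list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    abort(sprintf(
      "Malformed GMT line %d: expected at least 3 tab-separated fields, found %d.",
      bad[1], lengths(fields)[bad[1]]
    ))
  }
  geneset_collection(
    set_id = vapply(fields, `[[`, character(1), 1L),
    name = vapply(fields, `[[`, character(1), 2L),
    genes = lapply(fields, function(f) f[-(1:2)])
  )
}

#' Write a gene-set collection to a GMT file
#'
#' @param coll A [geneset_collection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  lines <- purrr::pmap_chr(
    list(coll$set_id, coll$name, coll$genes),
    function(id, nm, g) paste(c(id, nm, g), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Gene universe of a collection
#'
#' @param coll A [geneset_collection()].
#' @return Character vector: the union of all member gene sets.
#' @export
gene_universe <- function(coll) {
  unique(unlist(coll$genes, use.names = FALSE)) %||% character()
}

#' Filter gene sets by size
#'
#' Retains sets whose member count lies in `[min_size, max_size]`
#' (inclusive). MSigDB-style collections are conventionally restricted to
#' sets of 20-400 genes before enrichment testing.
#'
#' @param coll A [geneset_collection()].
#' @param min_size,max_size Inclusive size bounds, `1 <= min_size <= max_size`.
#' @return The filtered collection.
#' @export
filter_by_size <- function(coll, min_size = 20, max_size = 400) {
  check_scalar_int(min_size, "min_size", min = 1)
  check_scalar_int(max_size, "max_size", min = 1)
  if (min_size > max_size) abort("`min_size` must be <= `max_size`.")
  keep <- coll$size >= min_size & coll$size <= max_size
  geneset_collection(coll$set_id[keep], coll$name[keep], coll$genes[keep])
}

#' Restrict a collection to measured genes
#'
#' Intersects every set with the genes measured on an expression platform,
#' so that enrichment universes match the data. Sets that become empty are
#' dropped with a warning. Size filtering is not re-applied; callers that
#' want the size filter to count only measured genes should re-apply
#' [filter_by_size()] afterwards.
#'
#' @param coll A [geneset_collection()].
#' @param measured Non-empty character vector of measured gene symbols.
#' @return The restricted collection.
#' @export
restrict_to_measured <- function(coll, measured) {
  measured <- as.character(measured)
  if (length(measured) == 0L) abort("`measured` must be non-empty.")
  genes <- lapply(coll$genes, function(g) g[g %in% measured])
  keep <- lengths(genes) > 0L
  if (any(!keep)) {
    warn(sprintf(
      "%d gene set(s) dropped: no member genes among the measured genes.",
      sum(!keep)
    ))
  }
  geneset_collection(coll$set_id[keep], coll$name[keep], genes[keep])
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf(
    "<geneset_collection> %d sets, %d genes in universe\n",
    nrow(x), length(gene_universe(x))
  ))
  NextMethod()
}
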