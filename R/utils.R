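# Internal helpers: deterministic seed derivation and argument checks.

#' Derive a reproducible child seed from a master seed and context labels
#'
#' Folds the master seed together with an arbitrary sequence of labels
#' (dataset id, method, sub-dataset size, replicate index, ...) into a
#' 31-bit integer, so that every replicate of an experiment draws from its
#' own reproducible random stream and replicates are independent of
#' execution order.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric labels identifying the stream.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(17, "GSE0", "afc", 6, 1)
#' @export
derive_seed <- function(seed, ...) {
  labels <- unlist(lapply(list(...), as.character), use.names = FALSE)
  codes <- c(seed %% 2147483647, unlist(lapply(labels, utf8ToInt)))
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

check_scalar_int <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single integer.", name))
  }
  if (x < min) abort(sprintf("`%s` must be >= %s.", name, min))
  invisible(as.integer(x))
}
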