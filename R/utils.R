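# Evaluate code under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.  All stochastic steps in the package route
# through this so a single integer seed makes runs reproducible.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one master seed, stable across
# platforms and kept inside the 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# ordered class pairs (canonical class order, first < second)
class_pairs <- function(classes = AGN_CLASSES) {
  cmb <- utils::combn(classes, 2)
  lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
}

pair_key <- function(pair) paste(pair, collapse = "|")

# resolve sequences-or-matrix input into a staple feature matrix
as_feature_matrix <- function(x, feature_names_ref = NULL) {
  if (is.character(x)) x <- staple_features(x)
  x <- as.matrix(x)
  if (!is.null(feature_names_ref)) {
    if (ncol(x) != length(feature_names_ref))
      stop("feature matrix has ", ncol(x), " columns, model expects ",
           length(feature_names_ref), call. = FALSE)
    if (!is.null(colnames(x)) &&
        !identical(colnames(x), feature_names_ref))
      x <- x[, feature_names_ref, drop = FALSE]
  }
  storage.mode(x) <- "double"
  x
}
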