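#' Derive a reproducible sequence of sub-seeds from one master seed
#'
#' Stages and iterations each consume their own seed so that any stage can be
#' re-run in isolation and still reproduce the full-pipeline result.
#'
#' @param master_seed Integer master seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper around [mclust::adjustedRandIndex()] so downstream code and
#' tests agree on one implementation.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar ARI.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' Stratified fold assignment
#'
#' @param y Class labels.
#' @param n_folds Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids (1..n_folds) aligned with `y`.
#' @keywords internal
stratified_folds <- function(y, n_folds, seed) {
  y <- as.character(y)
  fold <- integer(length(y))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Evaluate an expression with a private RNG state seeded by `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
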