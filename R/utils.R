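#' Evaluate an expression with a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's
#' `.Random.seed` afterwards, so package functions with a `seed` argument
#' never perturb the global random stream. With `seed = NULL` the
#' expression runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a global seed
#'
#' Fixed affine derivation so each pipeline stage consumes an independent
#' stream; adding permutations to one stage does not perturb another.
#' Result is kept inside the 32-bit integer range.
#'
#' @param seed Global integer seed.
#' @param stage Small integer stage offset (>= 1).
#' @return Integer seed.
#' @keywords internal
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + stage * 8191) %% 2147483629)
}

# lower-triangle index pairs (i > j, column-major: same ordering as a
# `dist` vector)
lower_pairs <- function(n) {
  j <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  i <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

# dist object -> full symmetric matrix with labels
dist_matrix <- function(d) {
  m <- as.matrix(d)
  if (is.null(rownames(m))) {
    lab <- as.character(seq_len(nrow(m)))
    dimnames(m) <- list(lab, lab)
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
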