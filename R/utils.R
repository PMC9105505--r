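# internal helpers shared across modules

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Euclidean norms of the rows of a matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Squared distances between every row of a (n x 3) and every row of b (m x 3);
# returns n x m matrix. Memory ~ n*m doubles: callers keep blocks small.
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
}

cross_dist <- function(a, b) sqrt(pmax(cross_dist2(a, b), 0))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
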