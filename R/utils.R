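# Internal numeric helpers shared across modules.

#' @importFrom stats approx aggregate chisq.test cor rnorm rpois runif sd
#'   setNames t.test var
#' @importFrom utils combn write.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# log(sum(exp(x))) computed stably; returns -Inf for all--Inf input.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix (column count is small; loop over columns
# with pmax to stay in C code).
row_logsumexp <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  fin <- is.finite(mx)
  out <- mx
  if (any(fin)) {
    out[fin] <- mx[fin] + log(rowSums(exp(m[fin, , drop = FALSE] - mx[fin])))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
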