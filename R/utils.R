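# internal helpers

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  All stochastic generators in the package route
# through this so that identical (config, seed) pairs are byte-reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# population central moments (1/N denominator)
central_moment <- function(x, k) {
  mean((x - mean(x))^k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# shoelace area of a closed polygon given vertex matrix (n x 2); vertices
# need not repeat the first point
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# closed polyline length (first vertex implicitly repeated at the end)
polyline_length_closed <- function(v) {
  d <- v - v[c(2:nrow(v), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}
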