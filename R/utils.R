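# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All exported stochastic operations funnel
# through this so a single integer seed makes them reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Row-wise Euclidean norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Normalize rows to unit length.
normalize_rows <- function(m) {
  n <- row_norms(m)
  if (any(n < 1e-12)) abort("cannot normalize zero-length vectors")
  m / n
}

# Wrap angles into (-pi, pi].
wrap_angle <- function(a) {
  out <- a %% (2 * pi)
  big <- !is.na(out) & out > pi
  out[big] <- out[big] - 2 * pi
  out
}

# Smallest absolute difference between two angles on the circle.
angle_diff <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
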