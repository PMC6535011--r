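# Internal helpers shared across modules.

## Evaluate expr under a fixed RNG seed without disturbing the caller's
## random-number stream: generators promise bit-identical output per seed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## mean-0, sd-1 standardization over non-NA entries
standardize <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mu) / s
}

## upper-triangle (off-diagonal) values of a square matrix
upper_vals <- function(m) m[upper.tri(m)]

check_square_symmetric <- function(m, label = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(label, " must be a square matrix")
  if (max(abs(m - t(m))) > tol)
    stop(label, " must be symmetric")
  invisible(TRUE)
}
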