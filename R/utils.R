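#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the previous global RNG
#' state so that seeded generators do not disturb the caller's random
#' stream. A `NULL` seed evaluates `expr` against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# round-half-away-from-zero, the convention used for integer fold changes
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

# symmetric-matrix pseudo-inverse dropping exactly `n_zero` null modes;
# errors if the spectrum does not show that many (near-)zero eigenvalues
psdinv <- function(m, n_zero, tol = 1e-8) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  thresh <- tol * max(abs(e$values))
  zero <- abs(e$values) < thresh
  if (sum(zero) != n_zero) {
    stop_("expected %d zero mode(s) but found %d (disconnected network or degenerate geometry?)",
          n_zero, sum(zero))
  }
  if (any(e$values < -thresh)) {
    stop_("matrix is not positive semi-definite (min eigenvalue %.3g)", min(e$values))
  }
  inv <- ifelse(zero, 0, 1 / e$values)
  list(pinv = e$vectors %*% (inv * t(e$vectors)),
       values = e$values, vectors = e$vectors, zero = zero)
}
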