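# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All user-facing randomness goes through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# PSD check with a trace-relative tolerance for the smallest eigenvalue.
is_psd <- function(m, tol_factor = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(diag(m))
  min(ev) >= -tol_factor * max(tr, 1)
}

symmetrize <- function(m) (m + t(m)) / 2

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Draw n samples from N(0, Sigma) via eigendecomposition (tolerates PSD
# matrices that are singular, e.g. a zeroed covariance).
rmvn <- function(n, sigma) {
  k <- nrow(sigma)
  e <- eigen(symmetrize(sigma), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * k), n, k)
  z %*% (t(e$vectors) * sqrt(ev))
}
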