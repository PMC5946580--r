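#' Structured antedependence (SAD) specification for one random effect
#'
#' A SAD model of order \eqn{\alpha} expresses an effect at time
#' \eqn{w_j} as a regression on its \eqn{\alpha} preceding values plus an
#' innovation:
#' \deqn{u(w_j) = \sum_{s=1}^{\alpha} \theta_{s,j}\, u(w_{j-s}) + e(w_j),
#'       \quad e(w_j) \sim N(0, \sigma^2(w_j)).}
#' Each lag-specific antedependence coefficient \eqn{\theta_{s,j}} is a
#' polynomial in time of degree \eqn{\beta_s}, and the innovation variance is
#' \eqn{\sigma^2(w_j) = \exp(\mathrm{poly}_\gamma(w_j))}. The conventional
#' name of the structure is \code{SAD<alpha>-<beta_1...beta_alpha><gamma>},
#' e.g. `SAD1-11`.
#'
#' @param antedependence List of [poly_fn()] objects, one per lag (may be
#'   empty for order 0).
#' @param innovation_logvar A [poly_fn()] for the log innovation variance.
#' @return An object of class `sad_spec`.
#' @examples
#' sp <- sad_spec(list(poly_fn(c(0.3, 0.05))), poly_fn(c(1, 0.2)))
#' sad_name(sp)  # "SAD1-11"
#' @export
sad_spec <- function(antedependence = list(), innovation_logvar) {
  if (inherits(antedependence, "poly_fn")) antedependence <- list(antedependence)
  stopifnot(is.list(antedependence),
            all(vapply(antedependence, inherits, TRUE, "poly_fn")),
            inherits(innovation_logvar, "poly_fn"))
  structure(list(order = length(antedependence),
                 antedependence = antedependence,
                 innovation_logvar = innovation_logvar),
            class = "sad_spec")
}

#' @export
print.sad_spec <- function(x, ...) {
  cat(sprintf("<sad_spec %s>\n", sad_name(x)))
  invisible(x)
}

#' Conventional name of a SAD structure
#'
#' @param spec A [sad_spec()] or [cross_sad_spec()].
#' @return Character scalar such as `"SAD1-11"`; for a correlated pair the
#'   two names are joined with the cross-function degree, e.g.
#'   `"SAD1-11 x SAD1-11, cross degree 1"`.
#' @export
sad_name <- function(spec) {
  if (inherits(spec, "cross_sad_spec")) {
    return(sprintf("%s x %s, cross degree %d",
                   sad_name(spec$primary), sad_name(spec$secondary),
                   spec$cross$degree))
  }
  degs <- vapply(spec$antedependence, function(f) f$degree, 0L)
  sprintf("SAD%d-%s%d", spec$order,
          paste(degs, collapse = ""), spec$innovation_logvar$degree)
}

#' Correlated-pair SAD specification (direct and indirect genetic effects)
#'
#' Couples two SAD processes: the primary effect (direct genetic effect,
#' DGE) regresses on its own lags *and* on the same-week value of the
#' secondary effect (indirect genetic effect, IGE) through the
#' cross-antedependence function \eqn{\delta_j}:
#' \deqn{DGE(w_j) = \sum_s \theta_{s,j} DGE(w_{j-s}) + \delta_j IGE(w_j)
#'       + e_{D}(w_j),}
#' \deqn{IGE(w_j) = \sum_s \theta'_{s,j} IGE(w_{j-s}) + e_{I}(w_j).}
#'
#' @param primary [sad_spec()] for the primary (direct) effect.
#' @param secondary [sad_spec()] for the secondary (indirect) effect.
#' @param cross [poly_fn()] for the cross-antedependence \eqn{\delta_j}.
#' @return An object of class `cross_sad_spec`.
#' @export
cross_sad_spec <- function(primary, secondary, cross) {
  stopifnot(inherits(primary, "sad_spec"), inherits(secondary, "sad_spec"),
            inherits(cross, "poly_fn"))
  structure(list(primary = primary, secondary = secondary, cross = cross),
            class = "cross_sad_spec")
}

#' @export
print.cross_sad_spec <- function(x, ...) {
  cat(sprintf("<cross_sad_spec %s>\n", sad_name(x)))
  invisible(x)
}

#' Innovation variances on a grid
#'
#' @param spec A [sad_spec()].
#' @param grid A [time_grid()].
#' @return Strictly positive numeric vector \eqn{\sigma^2(w_j)}.
#' @export
innovation_variances <- function(spec, grid) {
  lv <- eval_poly(spec$innovation_logvar, grid)
  if (any(lv > 700)) {
    stopf("innovation log-variance overflows exp() (max %.1f)", max(lv))
  }
  exp(lv)
}

#' Antedependence L and innovation D matrices of a SAD structure
#'
#' Builds the unit lower-triangular matrix `L` (ones on the diagonal,
#' \eqn{-\theta_{s,j}} at position `(j, j-s)`) and the diagonal innovation
#' variance matrix `D`, so that the effect covariance is
#' \eqn{\Sigma = (L' D^{-1} L)^{-1}}. For early times `j <= order` the
#' recursion is truncated to the available lags.
#'
#' @inheritParams innovation_variances
#' @return List with dense matrices `L` and `D`.
#' @export
build_L_D <- function(spec, grid) {
  J <- length(grid_points(grid))
  L <- diag(J)
  if (spec$order > 0L) {
    for (s in seq_len(spec$order)) {
      th <- eval_poly(spec$antedependence[[s]], grid)
      for (j in seq_len(J)) {
        if (j - s >= 1L) L[j, j - s] <- -th[j]
      }
    }
  }
  list(L = L, D = diag(innovation_variances(spec, grid), J))
}

#' Effect covariance from antedependence factors
#'
#' \eqn{\Sigma = (L' D^{-1} L)^{-1}}, symmetrized to remove round-off
#' asymmetry. Equals the covariance of the forward SAD recursion started
#' from its first innovation.
#'
#' @param L Unit lower-triangular matrix.
#' @param D Diagonal matrix of positive innovation variances.
#' @return Symmetric covariance matrix.
#' @export
sigma_from_LD <- function(L, D) {
  d <- diag(D)
  stopifnot(all(d > 0))
  Linv <- backsolve(t(L), diag(nrow(L)))  # L^{-1} via triangular solve
  Linv <- t(Linv)
  symmetrize(Linv %*% (d * t(Linv)))
}

#' Covariance matrix implied by a SAD specification
#'
#' Convenience wrapper: `sad_sigma(spec, grid)` returns the J x J (single
#' effect) or 2J x 2J (correlated pair, blocks ordered
#' `[primary w1..wJ, secondary w1..wJ]`) covariance matrix.
#'
#' @param spec A [sad_spec()] or [cross_sad_spec()].
#' @param grid A [time_grid()].
#' @export
sad_sigma <- function(spec, grid) {
  if (inherits(spec, "cross_sad_spec")) return(build_cross_sigma(spec, grid))
  ld <- build_L_D(spec, grid)
  s <- sigma_from_LD(ld$L, ld$D)
  w <- grid_points(grid)
  dimnames(s) <- list(paste0("w", w), paste0("w", w))
  s
}

#' Joint covariance of a correlated DGE/IGE pair
#'
#' Builds the joint antedependence system in the internal variable order
#' (secondary w1..wJ, primary w1..wJ), in which the primary effect may
#' reference the same-week secondary value through \eqn{-\delta_j} while the
#' system stays lower-triangular, then inverts and reorders the result to
#' blocks `[primary (DGE), secondary (IGE)]`. With \eqn{\delta \equiv 0} the
#' result is exactly block-diagonal in the two marginal SAD covariances.
#'
#' @param spec A [cross_sad_spec()].
#' @param grid A [time_grid()].
#' @return 2J x 2J symmetric covariance matrix, DGE block first.
#' @export
build_cross_sigma <- function(spec, grid) {
  J <- length(grid_points(grid))
  ldP <- build_L_D(spec$primary, grid)
  ldS <- build_L_D(spec$secondary, grid)
  delta <- eval_poly(spec$cross, grid)

  # joint order: secondary 1..J, then primary 1..J
  L <- matrix(0, 2L * J, 2L * J)
  L[seq_len(J), seq_len(J)] <- ldS$L
  L[J + seq_len(J), J + seq_len(J)] <- ldP$L
  for (j in seq_len(J)) L[J + j, j] <- -delta[j]
  D <- diag(c(diag(ldS$D), diag(ldP$D)), 2L * J)

  sig <- sigma_from_LD(L, D)
  perm <- c(J + seq_len(J), seq_len(J))  # primary block first
  sig <- sig[perm, perm]
  w <- grid_points(grid)
  nm <- c(paste0("DGE.w", w), paste0("IGE.w", w))
  dimnames(sig) <- list(nm, nm)
  sig
}

#' Refactor a covariance matrix into antedependence form
#'
#' Inverse of [sigma_from_LD()] at full order: sequential regressions of
#' each time point on all preceding ones give the antedependence
#' coefficients theta (row j holds \eqn{\theta_{s,j}} for lag s) and the
#' innovation variances d. Restricting to `order` keeps only the first
#' `order` lags (the remaining coefficients are the full-order ones, which
#' are zero whenever Sigma is exactly of that order).
#'
#' @param sigma Symmetric positive-definite covariance matrix.
#' @return List with `theta` (J x (J-1) matrix, `theta[j, s]` = lag-s
#'   coefficient at time j) and `d` (length-J innovation variances).
#' @export
sad_decompose <- function(sigma) {
  J <- nrow(sigma)
  theta <- matrix(0, J, max(J - 1L, 1L))
  d <- numeric(J)
  d[1] <- sigma[1, 1]
  if (J > 1L) {
    for (j in 2:J) {
      prev <- seq_len(j - 1L)
      b <- solve(sigma[prev, prev, drop = FALSE], sigma[prev, j])
      # b[k] regresses on time k; lag s = j - k
      theta[j, j - prev] <- b
      d[j] <- sigma[j, j] - sum(b * sigma[prev, j])
    }
  }
  list(theta = theta, d = d)
}

#' Simulate trajectories from a SAD specification
#'
#' Draws i.i.d. trajectories through the forward recursion; the empirical
#' covariance converges to [sad_sigma()] as `n` grows. For a
#' [cross_sad_spec()] the result has 2J columns ordered
#' `[primary (DGE) w1..wJ, secondary (IGE) w1..wJ]`.
#'
#' @param spec A [sad_spec()] or [cross_sad_spec()].
#' @param grid A [time_grid()].
#' @param n Number of trajectories.
#' @param seed Optional integer seed.
#' @return `n x J` (or `n x 2J`) matrix.
#' @export
sample_effect <- function(spec, grid, n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    J <- length(grid_points(grid))
    if (inherits(spec, "cross_sad_spec")) {
      ige <- sample_single(spec$secondary, grid, n)
      delta <- eval_poly(spec$cross, grid)
      dge <- matrix(0, n, J)
      th <- lapply(spec$primary$antedependence, eval_poly, grid = grid)
      vr <- innovation_variances(spec$primary, grid)
      for (j in seq_len(J)) {
        x <- delta[j] * ige[, j] + stats::rnorm(n, sd = sqrt(vr[j]))
        if (spec$primary$order > 0L) {
          for (s in seq_len(spec$primary$order)) {
            if (j - s >= 1L) x <- x + th[[s]][j] * dge[, j - s]
          }
        }
        dge[, j] <- x
      }
      cbind(dge, ige)
    } else {
      sample_single(spec, grid, n)
    }
  })
}

sample_single <- function(spec, grid, n) {
  J <- length(grid_points(grid))
  vr <- innovation_variances(spec, grid)
  th <- lapply(spec$antedependence, eval_poly, grid = grid)
  out <- matrix(0, n, J)
  for (j in seq_len(J)) {
    x <- stats::rnorm(n, sd = sqrt(vr[j]))
    if (spec$order > 0L) {
      for (s in seq_len(spec$order)) {
        if (j - s >= 1L) x <- x + th[[s]][j] * out[, j - s]
      }
    }
    out[, j] <- x
  }
  out
}
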