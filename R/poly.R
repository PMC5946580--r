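#' Polynomial parameter function
#'
#' SAD model parameters (antedependence coefficients, log innovation
#' variances, cross-antedependence coefficients) are low-degree polynomials
#' of the measurement time. A `poly_fn` stores the coefficients with the
#' constant term first.
#'
#' @param coefficients Numeric vector of length `degree + 1`, constant term
#'   first.
#' @return An object of class `poly_fn`.
#' @examples
#' f <- poly_fn(c(0.1, 0.2))   # 0.1 + 0.2 * w
#' eval_poly(f, time_grid(1:5))
#' @export
poly_fn <- function(coefficients) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) < 1L || anyNA(coefficients)) {
    stopf("poly_fn needs at least one finite coefficient")
  }
  structure(list(degree = length(coefficients) - 1L,
                 coefficients = coefficients),
            class = "poly_fn")
}

#' @export
print.poly_fn <- function(x, ...) {
  cat(sprintf("<poly_fn degree %d: %s>\n", x$degree,
              paste(signif(x$coefficients, 4), collapse = ", ")))
  invisible(x)
}

#' Measurement-time grid
#'
#' Ordered vector of measurement times (here: week indices 1..5). An
#' optional affine transform `a + b*w` is applied before polynomials are
#' evaluated, so alternative time codings (centering, scaling) can be used
#' without touching the polynomial coefficients.
#'
#' @param weeks Strictly increasing numeric vector of measurement times.
#' @param transform Optional numeric `c(a, b)`; polynomials are evaluated at
#'   `a + b * weeks`. Default is the identity.
#' @return An object of class `time_grid`.
#' @export
time_grid <- function(weeks, transform = c(0, 1)) {
  weeks <- as.numeric(weeks)
  if (length(weeks) < 1L || anyNA(weeks)) stopf("time grid must be non-empty")
  if (is.unsorted(weeks, strictly = TRUE)) {
    stopf("time grid must be strictly increasing")
  }
  structure(list(weeks = weeks, transform = as.numeric(transform)),
            class = "time_grid")
}

grid_points <- function(grid) {
  if (inherits(grid, "time_grid")) {
    grid$transform[1] + grid$transform[2] * grid$weeks
  } else {
    as.numeric(grid)
  }
}

#' Evaluate a polynomial parameter function on a time grid
#'
#' @param fn A [poly_fn()].
#' @param grid A [time_grid()] or numeric vector of times.
#' @return Numeric vector, one value per grid point.
#' @export
eval_poly <- function(fn, grid) {
  stopifnot(inherits(fn, "poly_fn"))
  w <- grid_points(grid)
  out <- rep(fn$coefficients[1], length(w))
  if (fn$degree > 0L) {
    for (q in seq_len(fn$degree)) {
      out <- out + fn$coefficients[q + 1L] * w^q
    }
  }
  out
}
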