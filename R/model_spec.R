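#' Model specification for the residual-free SAD mixed model
#'
#' Defines the random-effect structure of the longitudinal model
#' \deqn{y_{ilm}(w_j) = \mu_i(w_j) + DGE_i(w_j) + \sum_{k \in K_i} IGE_k(w_j)
#'   + l_l(w_j) + g_m(w_j) + p_i(w_j),}
#' where the direct genetic effect (DGE) of an animal acts on its own
#' records and the indirect genetic effect (IGE) of each of its group mates
#' acts on the focal record. The model carries no explicit residual: the
#' pseudo-permanent animal effect `p` absorbs it, so every record's
#' "residual" covariance is the permanent-effect covariance of its animal.
#'
#' Each random effect carries a SAD covariance structure over the week
#' grid; the genetic term is either a correlated DGE/IGE pair
#' ([cross_sad_spec()]) or a DGE-only [sad_spec()].
#'
#' @param genetic [cross_sad_spec()] (DGE+IGE) or [sad_spec()] (DGE only);
#'   `NULL` fits a purely environmental model (no pedigree needed), mainly
#'   useful for oracle checks and baseline comparisons.
#' @param group [sad_spec()] for the group (cage) effect.
#' @param permanent [sad_spec()] for the pseudo-permanent animal effect.
#' @param litter Optional [sad_spec()] for the litter effect (`NULL` to
#'   omit, as in the selection simulation).
#' @param fixed Fixed-effect formula evaluated on the phenotype table;
#'   default a week-factor mean.
#' @param grid [time_grid()] of measurement weeks.
#' @return An object of class `sad_model`.
#' @seealso [default_sad_model()] for the standard SAD1-11 configuration.
#' @export
sad_model <- function(genetic, group, permanent, litter = NULL,
                      fixed = ~ 0 + factor(week), grid = time_grid(1:5)) {
  stopifnot(is.null(genetic) || inherits(genetic, "sad_spec") ||
              inherits(genetic, "cross_sad_spec"),
            inherits(group, "sad_spec"), inherits(permanent, "sad_spec"),
            is.null(litter) || inherits(litter, "sad_spec"),
            inherits(grid, "time_grid"))
  structure(list(genetic = genetic, group = group, permanent = permanent,
                 litter = litter, fixed = fixed, grid = grid,
                 include_ige = inherits(genetic, "cross_sad_spec")),
            class = "sad_model")
}

#' @export
print.sad_model <- function(x, ...) {
  cat("<sad_model>\n")
  if (!is.null(x$genetic)) {
    cat("  genetic:  ", sad_name(x$genetic),
        if (x$include_ige) "(DGE + IGE)" else "(DGE only)", "\n")
  }
  if (!is.null(x$litter)) cat("  litter:   ", sad_name(x$litter), "\n")
  cat("  group:    ", sad_name(x$group), "\n")
  cat("  permanent:", sad_name(x$permanent), "\n")
  cat("  fixed:    ", deparse(x$fixed), "\n")
  cat("  parameters:", n_params(x), "\n")
  invisible(x)
}

#' Standard SAD1-11 model
#'
#' The configuration retained for the longitudinal growth analysis:
#' SAD1-11 for every random-effect function (order-1 antedependence with a
#' degree-1 polynomial, degree-1 log innovation variance) and, when IGE are
#' included, a degree-1 cross-antedependence function.
#'
#' @param include_ige Include the indirect genetic effect (default `TRUE`).
#' @param litter Include a litter effect (default `FALSE`, matching the
#'   selection simulation; the full data model sets it `TRUE`).
#' @inheritParams sad_model
#' @export
default_sad_model <- function(include_ige = TRUE, litter = FALSE,
                              fixed = ~ 0 + factor(week),
                              grid = time_grid(1:5)) {
  sad11 <- function() sad_spec(list(poly_fn(c(0, 0))), poly_fn(c(0, 0)))
  genetic <- if (include_ige) {
    cross_sad_spec(sad11(), sad11(), poly_fn(c(0, 0)))
  } else {
    sad11()
  }
  sad_model(genetic = genetic, group = sad11(), permanent = sad11(),
            litter = if (litter) sad11() else NULL,
            fixed = fixed, grid = grid)
}

# --- parameter vector packing ------------------------------------------------
# Documented order of the concatenated parameter vector omega:
#   genetic pair:  DGE antedependence (lag 1..alpha), IGE antedependence,
#                  cross delta, DGE log innovation variance, IGE log
#                  innovation variance
#   genetic single: antedependence, log innovation variance
#   then litter (if present), group, permanent: antedependence, log
#   innovation variance each.

spec_coefs <- function(spec) {
  if (inherits(spec, "cross_sad_spec")) {
    c(unlist(lapply(spec$primary$antedependence, `[[`, "coefficients")),
      unlist(lapply(spec$secondary$antedependence, `[[`, "coefficients")),
      spec$cross$coefficients,
      spec$primary$innovation_logvar$coefficients,
      spec$secondary$innovation_logvar$coefficients)
  } else {
    c(unlist(lapply(spec$antedependence, `[[`, "coefficients")),
      spec$innovation_logvar$coefficients)
  }
}

spec_set_coefs <- function(spec, x) {
  take <- function(k) {
    v <- x[seq_len(k)]
    x <<- x[-seq_len(k)]
    v
  }
  if (inherits(spec, "cross_sad_spec")) {
    for (s in seq_along(spec$primary$antedependence)) {
      spec$primary$antedependence[[s]] <-
        poly_fn(take(spec$primary$antedependence[[s]]$degree + 1L))
    }
    for (s in seq_along(spec$secondary$antedependence)) {
      spec$secondary$antedependence[[s]] <-
        poly_fn(take(spec$secondary$antedependence[[s]]$degree + 1L))
    }
    spec$cross <- poly_fn(take(spec$cross$degree + 1L))
    spec$primary$innovation_logvar <-
      poly_fn(take(spec$primary$innovation_logvar$degree + 1L))
    spec$secondary$innovation_logvar <-
      poly_fn(take(spec$secondary$innovation_logvar$degree + 1L))
  } else {
    for (s in seq_along(spec$antedependence)) {
      spec$antedependence[[s]] <- poly_fn(take(spec$antedependence[[s]]$degree + 1L))
    }
    spec$innovation_logvar <- poly_fn(take(spec$innovation_logvar$degree + 1L))
  }
  list(spec = spec, rest = x)
}

model_terms <- function(model) {
  terms <- list()
  if (!is.null(model$genetic)) terms$genetic <- model$genetic
  if (!is.null(model$litter)) terms$litter <- model$litter
  terms$group <- model$group
  terms$permanent <- model$permanent
  terms
}

#' Extract the packed parameter vector of a model
#'
#' @param model A [sad_model()].
#' @return Named numeric vector in the documented packing order.
#' @export
pack_params <- function(model) {
  terms <- model_terms(model)
  out <- unlist(lapply(terms, spec_coefs))
  names(out) <- unlist(lapply(names(terms), function(nm) {
    paste0(nm, ".", seq_along(spec_coefs(terms[[nm]])))
  }))
  out
}

#' Replace the parameters of a model with a packed vector
#'
#' @param model A [sad_model()].
#' @param omega Numeric vector as produced by [pack_params()].
#' @return The model with updated polynomial coefficients.
#' @export
set_params <- function(model, omega) {
  stopifnot(length(omega) == n_params(model))
  x <- as.numeric(omega)
  for (nm in c("genetic", "litter", "group", "permanent")) {
    if (is.null(model[[nm]])) next
    res <- spec_set_coefs(model[[nm]], x)
    model[[nm]] <- res$spec
    x <- res$rest
  }
  model
}

#' Number of free parameters of a model
#'
#' @param model A [sad_model()].
#' @export
n_params <- function(model) length(unlist(lapply(model_terms(model), spec_coefs)))
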