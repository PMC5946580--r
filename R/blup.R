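#' BLUP solutions at fixed variance components
#'
#' Solves the mixed-model equations at the given parameter vector and
#' returns fixed-effect estimates and random-effect solutions, including
#' per-animal, per-week estimated breeding values for the direct and (when
#' modelled) indirect genetic effects. Animals present in the pedigree but
#' without records receive EBVs through the relationship matrix.
#'
#' @param design A [build_design()] object (or a phenotype data frame, with
#'   `model` and `ped` supplied).
#' @param omega Packed parameter vector at which components are fixed
#'   (e.g. `fit$omega` from [fit_reml()]).
#' @param model,ped Used only when `design` is a data frame.
#' @return An object of class `sad_blup`: `fixed` (named vector), `ebv`
#'   (data frame animal/week/dge and, if modelled, ige), `group`, `litter`
#'   solutions, and the raw `solution` vector.
#' @export
predict_blup <- function(design, omega, model = NULL, ped = NULL) {
  if (is.data.frame(design)) {
    stopifnot(!is.null(model))
    design <- build_design(design, model, ped)
  }
  pieces <- mme_pieces(design, omega)
  if (is.null(pieces)) stopf("invalid parameter vector for BLUP")
  ch <- design_chol(design, pieces$C)
  if (is.null(ch)) stopf("mixed-model equations are singular")
  sol <- as.numeric(Matrix::solve(ch, pieces$rhs, system = "A"))

  p <- design$p
  J <- design$J
  K <- design$K
  weeks <- design$model$grid$weeks
  fixed <- stats::setNames(sol[seq_len(p)], colnames(design$X))

  ebv <- NULL
  if (!is.null(design$model$genetic)) {
    u_g <- sol[design$offsets[["genetic"]] + seq_len(design$nA * K)]
    gmat <- matrix(u_g, ncol = K, byrow = TRUE)  # animals x slots
    ebv <- data.frame(animal = rep(design$ped$animal, each = J),
                      week = rep(weeks, design$nA),
                      dge = as.vector(t(gmat[, seq_len(J), drop = FALSE])))
    if (design$model$include_ige) {
      ebv$ige <- as.vector(t(gmat[, J + seq_len(J), drop = FALSE]))
    }
  }

  group <- NULL
  if (design$n_group > 0L) {
    u <- sol[design$offsets[["group"]] + seq_len(design$n_group * J)]
    group <- data.frame(group = rep(design$grp_ids, each = J),
                        week = rep(weeks, design$n_group),
                        effect = u)
  }
  litter <- NULL
  if (!is.null(design$model$litter)) {
    u <- sol[design$offsets[["litter"]] + seq_len(design$n_litter * J)]
    litter <- data.frame(litter = rep(design$lit_ids, each = J),
                         week = rep(weeks, design$n_litter),
                         effect = u)
  }
  structure(list(fixed = fixed, ebv = ebv, group = group, litter = litter,
                 solution = sol),
            class = "sad_blup")
}

#' @export
print.sad_blup <- function(x, ...) {
  cat(sprintf("<sad_blup: %d fixed effects%s>\n", length(x$fixed),
              if (is.null(x$ebv)) "" else
                sprintf(", %d animals x %d weeks",
                        length(unique(x$ebv$animal)),
                        length(unique(x$ebv$week)))))
  invisible(x)
}

#' Total estimated breeding value per week
#'
#' For group size n, the total breeding value of an animal at a time point
#' combines its direct effect with its indirect effect expressed in each of
#' the n-1 group mates: `TEBV = dge + (n-1) * ige`.
#'
#' @param ebv_direct,ebv_indirect Numeric vectors (or matrices) of direct
#'   and indirect EBVs for matching animal/week entries.
#' @param group_size Number of animals per group (default 8).
#' @return TEBV values with the shape of the inputs.
#' @export
compute_tebv <- function(ebv_direct, ebv_indirect, group_size = 8) {
  stopifnot(length(ebv_direct) == length(ebv_indirect), group_size >= 2)
  ebv_direct + (group_size - 1) * ebv_indirect
}
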