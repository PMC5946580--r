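#' Total phenotypic variance under social interactions
#'
#' For groups of n animals with average within-group relatedness r, the
#' phenotypic variance at week j combines the direct and indirect genetic
#' variances, their covariance, and the environmental components:
#' \deqn{\sigma^2_{Tj} = \sigma^2_{DGEj} + (n-1)\sigma^2_{IGEj}
#'   + (n-1) r [2\sigma_{DGEj,IGEj} + (n-2)\sigma^2_{IGEj}]
#'   + \sigma^2_{lj} + \sigma^2_{gj} + \sigma^2_{pj},}
#' which at the default n = 8 is the printed 7/6-coefficient form.
#'
#' @param components List (or data frame) with per-week numeric vectors
#'   `dge_var`, `ige_var`, `dge_ige_cov`, `litter_var`, `group_var`,
#'   `perm_var` (missing environmental pieces default to 0).
#' @param n_group Group size (default 8).
#' @param r Average genetic relatedness among cage mates (the growth study
#'   reports 0.16; compute it from a pedigree with
#'   [mean_cage_relatedness()]).
#' @return Numeric vector of total phenotypic variances per week.
#' @export
total_phenotypic_variance <- function(components, n_group = 8, r = 0.16) {
  cp <- components
  J <- length(cp$dge_var)
  get0v <- function(nm) if (is.null(cp[[nm]])) numeric(J) else cp[[nm]]
  ige <- get0v("ige_var")
  cov <- get0v("dge_ige_cov")
  if (any(lengths(list(ige, cov)) != J)) stopf("component vectors differ in length")
  cp$dge_var + (n_group - 1) * ige +
    (n_group - 1) * r * (2 * cov + (n_group - 2) * ige) +
    get0v("litter_var") + get0v("group_var") + get0v("perm_var")
}

#' Extract per-week variance components from fitted covariance matrices
#'
#' @param sigma List with elements `genetic` (J x J or 2J x 2J, DGE block
#'   first), `group`, `permanent`, optionally `litter` — e.g. `fit$sigma`
#'   from [fit_reml()].
#' @return List of per-week component vectors suitable for
#'   [total_phenotypic_variance()] and [heritabilities()].
#' @export
variance_components <- function(sigma) {
  Sg <- sigma$genetic
  if (is.null(Sg)) {
    # purely environmental model: zero genetic components
    Sg <- matrix(0, nrow(sigma$permanent), nrow(sigma$permanent))
  }
  has_ige <- if (!is.null(rownames(Sg))) {
    any(grepl("^IGE", rownames(Sg)))
  } else {
    !is.null(sigma$permanent) && nrow(Sg) == 2L * nrow(sigma$permanent)
  }
  J <- if (has_ige) nrow(Sg) %/% 2L else nrow(Sg)
  out <- list(dge_var = unname(diag(Sg)[seq_len(J)]),
              ige_var = if (has_ige) unname(diag(Sg)[J + seq_len(J)]) else
                numeric(J),
              dge_ige_cov = if (has_ige)
                unname(diag(Sg[seq_len(J), J + seq_len(J), drop = FALSE])) else
                numeric(J),
              group_var = unname(diag(sigma$group)),
              perm_var = unname(diag(sigma$permanent)))
  out$litter_var <- if (!is.null(sigma$litter)) unname(diag(sigma$litter)) else
    numeric(J)
  out
}

#' Direct, indirect and total heritabilities per week
#'
#' Direct heritability is the ratio of the direct genetic variance to the
#' total phenotypic variance; indirect heritability uses the total
#' indirect genetic variance \eqn{(n-1)^2 \sigma^2_{IGE}} (49 at n = 8);
#' total heritability uses the total heritable variance
#' \deqn{\sigma^2_{TBVj} = \sigma^2_{DGEj} + 2(n-1)\sigma_{DGEj,IGEj}
#'   + (n-1)^2 \sigma^2_{IGEj}.}
#' Indirect and total ratios can exceed 1 or go negative in pathological
#' samples; they are reported unclamped.
#'
#' @inheritParams total_phenotypic_variance
#' @return Data frame with week, the three heritabilities, `total_var` and
#'   `tbv_var`.
#' @export
heritabilities <- function(components, n_group = 8, r = 0.16) {
  tv <- total_phenotypic_variance(components, n_group, r)
  if (any(tv <= 0)) stopf("non-positive total phenotypic variance")
  m <- n_group - 1
  tbv <- components$dge_var + 2 * m * components$dge_ige_cov +
    m^2 * components$ige_var
  data.frame(week = seq_along(tv),
             h2_direct = components$dge_var / tv,
             h2_indirect = m^2 * components$ige_var / tv,
             h2_total = tbv / tv,
             total_var = tv, tbv_var = tbv)
}

# Per-draw summaries used by the sampling machinery: rebuild all SAD
# covariances from omega and flag non-PSD reconstructions.
sampled_summaries <- function(model, omega, n_group, r, psd_tol = 1e-8) {
  m <- set_params(model, omega)
  grid <- m$grid
  sig <- list(group = sad_sigma(m$group, grid),
              permanent = sad_sigma(m$permanent, grid))
  if (!is.null(m$genetic)) {
    sig <- c(list(genetic = sad_sigma(m$genetic, grid)), sig)
  }
  if (!is.null(m$litter)) sig$litter <- sad_sigma(m$litter, grid)
  ok <- all(vapply(sig, is_psd, TRUE, tol_factor = psd_tol))
  list(sigma = sig, ok = ok,
       herit = if (ok) heritabilities(variance_components(sig), n_group, r) else NULL)
}

unique_components <- function(sig) {
  # stacked unique (co)variance elements of all effect matrices, fixed order
  out <- c()
  for (nm in c("genetic", "litter", "group", "permanent")) {
    S <- sig[[nm]]
    if (is.null(S)) next
    v <- S[upper.tri(S, diag = TRUE)]
    idx <- which(upper.tri(S, diag = TRUE), arr.ind = TRUE)
    names(v) <- paste0(nm, "[", idx[, 1], ",", idx[, 2], "]")
    out <- c(out, v)
  }
  out
}

#' Sampling-based standard errors of (co)variance and heritability estimates
#'
#' Draws parameter vectors from the large-sample distribution
#' \eqn{\tilde\omega \sim N(\hat\omega, H(\hat\omega))} with H the inverse
#' information at convergence, rebuilds every effect covariance matrix and
#' the heritabilities for each draw, and discards draws whose reconstructed
#' matrices are not positive semi-definite (smallest eigenvalue below
#' `-psd_tol` times the trace). Point estimates are the means across
#' retained draws and standard errors their standard deviations.
#'
#' @param fit A [fit_reml()] result.
#' @param info A [reml_info()] result for `fit` (computed if omitted).
#' @param n_samples Number of draws (default 10000).
#' @param n_group,r Passed to [heritabilities()].
#' @param seed Optional integer seed.
#' @param psd_tol Relative PSD tolerance.
#' @return Object of class `sad_sampling`: `heritability` (mean and SE per
#'   week), `components` (mean and SE of every unique (co)variance
#'   element), `n_retained`, `n_rejected`, and the point-estimate
#'   heritabilities `plugin`.
#' @export
mvn_sampling_se <- function(fit, info = NULL, n_samples = 10000,
                            n_group = 8, r = 0.16, seed = NULL,
                            psd_tol = 1e-8) {
  if (is.null(info)) info <- reml_info(fit)
  H <- info$H
  om <- fit$omega
  k <- length(om)
  eH <- eigen(symmetrize(H), symmetric = TRUE)
  ev <- pmax(eH$values, 0)
  root <- eH$vectors %*% (t(eH$vectors) * sqrt(ev))

  with_seed(seed, {
    draws <- matrix(stats::rnorm(n_samples * k), n_samples, k) %*% t(root)
    draws <- sweep(draws, 2, om, `+`)
    herit_acc <- NULL
    comp_acc <- NULL
    kept <- 0L
    for (i in seq_len(n_samples)) {
      sm <- tryCatch(sampled_summaries(fit$model, draws[i, ], n_group, r,
                                       psd_tol),
                     error = function(e) list(ok = FALSE))
      if (!isTRUE(sm$ok)) next
      kept <- kept + 1L
      hv <- c(sm$herit$h2_direct, sm$herit$h2_indirect, sm$herit$h2_total)
      cv <- unique_components(sm$sigma)
      if (is.null(herit_acc)) {
        herit_acc <- matrix(NA_real_, n_samples, length(hv))
        comp_acc <- matrix(NA_real_, n_samples, length(cv),
                           dimnames = list(NULL, names(cv)))
      }
      herit_acc[kept, ] <- hv
      comp_acc[kept, ] <- cv
    }
    if (kept == 0L) stopf("all %d samples produced non-PSD covariances", n_samples)
    if (kept < 100L) warning(sprintf("only %d of %d draws retained", kept, n_samples))
    herit_acc <- herit_acc[seq_len(kept), , drop = FALSE]
    comp_acc <- comp_acc[seq_len(kept), , drop = FALSE]

    J <- length(fit$model$grid$weeks)
    hm <- colMeans(herit_acc)
    hs <- apply(herit_acc, 2, stats::sd)
    herit <- data.frame(week = rep(fit$model$grid$weeks, 3),
                        measure = rep(c("direct", "indirect", "total"), each = J),
                        estimate = hm, se = hs)
    comp <- data.frame(component = colnames(comp_acc),
                       estimate = colMeans(comp_acc),
                       se = apply(comp_acc, 2, stats::sd),
                       row.names = NULL)
    plugin <- heritabilities(variance_components(fit$sigma), n_group, r)
    structure(list(heritability = herit, components = comp,
                   draws_components = comp_acc,
                   n_retained = kept, n_rejected = n_samples - kept,
                   plugin = plugin),
              class = "sad_sampling")
  })
}

#' @export
print.sad_sampling <- function(x, ...) {
  cat(sprintf("<sad_sampling: %d retained, %d rejected draws>\n",
              x$n_retained, x$n_rejected))
  print(x$heritability, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Correlations among (co)variance-component estimates and raw parameters
#'
#' Pearson correlations of every unique (co)variance element across the
#' retained draws of [mvn_sampling_se()] (the 100 x 100 matrix in the full
#' five-effect model), plus the parameter-estimate correlation matrix
#' derived directly from the inverse information. Entries with absolute
#' value above `flag_threshold` (default 0.6) are listed as potential
#' estimability problems.
#'
#' @param sampling A [mvn_sampling_se()] result.
#' @param info A [reml_info()] result (for the parameter-level matrix;
#'   optional).
#' @param flag_threshold Absolute-correlation flag level.
#' @return List with `component_correlations`, `param_correlations` (or
#'   `NULL`), and `flagged` (data frame of large component correlations).
#' @export
estimate_correlations <- function(sampling, info = NULL, flag_threshold = 0.6) {
  draws <- sampling$draws_components
  if (nrow(draws) < 100L) warning("fewer than 100 retained draws")
  sds <- apply(draws, 2, stats::sd)
  keep <- sds > 0
  cc <- matrix(NA_real_, ncol(draws), ncol(draws),
               dimnames = list(colnames(draws), colnames(draws)))
  cc[keep, keep] <- stats::cor(draws[, keep, drop = FALSE])
  diag(cc) <- 1
  idx <- which(abs(cc) > flag_threshold & upper.tri(cc), arr.ind = TRUE)
  flagged <- data.frame(a = rownames(cc)[idx[, 1]], b = colnames(cc)[idx[, 2]],
                        correlation = cc[idx])
  pc <- if (!is.null(info)) stats::cov2cor(info$H) else NULL
  list(component_correlations = cc, param_correlations = pc,
       flagged = flagged[order(-abs(flagged$correlation)), ])
}
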