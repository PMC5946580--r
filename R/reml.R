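#' Build the mixed-model design for a phenotype table
#'
#' Assembles incidence matrices and the precomputed cross-products used by
#' the REML likelihood and BLUP solvers. Records are validated (one record
#' per animal and week, every animal in the pedigree, weeks on the model's
#' grid), sorted animal-major, and linked to their group mates: the IGE
#' incidence row of a record carries a 1 for each group mate *present in
#' the cage that week*.
#'
#' Because the model has no explicit residual, the pseudo-permanent effect
#' plays the role of a correlated within-animal residual: its covariance
#' enters the likelihood as a block-diagonal R with one
#' \eqn{\Sigma_p[\mathrm{obs},\mathrm{obs}]} block per animal.
#'
#' @param records Phenotype data frame with columns `animal`, `group`,
#'   `week`, `adg` (plus `litter` when the model includes a litter effect,
#'   and any fixed-effect covariates).
#' @param model A [sad_model()].
#' @param ped A [pedigree()] covering every animal with records.
#' @return An object of class `sad_design` (an environment) holding the
#'   incidence structure; pass it to [reml_loglik()], [fit_reml()] or
#'   [predict_blup()].
#' @export
build_design <- function(records, model, ped = NULL) {
  stopifnot(inherits(model, "sad_model"),
            is.null(model$genetic) || inherits(ped, "pedigree"))
  need <- c("animal", "group", "week", "adg")
  if (!is.null(model$litter)) need <- c(need, "litter")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("records missing column(s): %s", paste(miss, collapse = ", "))

  records <- as.data.frame(records)
  records$animal <- as.character(records$animal)
  weeks <- model$grid$weeks
  J <- length(weeks)
  wk <- match(records$week, weeks)
  if (anyNA(wk)) stopf("record week not on the model grid: %s",
                       records$week[which(is.na(wk))[1]])
  key <- paste(records$animal, wk)
  if (anyDuplicated(key)) {
    stopf("duplicate animal x week record: %s", key[duplicated(key)][1])
  }
  anim_ids <- if (!is.null(model$genetic)) ped$animal else
    sort(unique(records$animal))
  apos <- match(records$animal, anim_ids)
  if (anyNA(apos)) stopf("animal with phenotype missing from pedigree: %s",
                         records$animal[which(is.na(apos))[1]])

  ord <- order(apos, wk)
  records <- records[ord, , drop = FALSE]
  wk <- wk[ord]
  apos <- apos[ord]
  n <- nrow(records)
  y <- as.numeric(records$adg)
  if (anyNA(y)) stopf("non-numeric or missing adg value")

  # fixed effects, reduced to full column rank
  X <- stats::model.matrix(model$fixed, data = records)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning(sprintf("dropping %d aliased fixed-effect column(s)",
                    ncol(X) - qx$rank))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  p <- ncol(X)

  nA <- if (!is.null(model$genetic)) nrow(ped) else 0L
  K <- if (model$include_ige) 2L * J else J

  blocks <- list(Matrix::Matrix(X, sparse = TRUE))
  offsets <- c(fixed = 0L)
  qtot <- p
  if (!is.null(model$genetic)) {
    # genetic incidence: DGE own animal x week; IGE one column per mate
    gi <- seq_len(n)
    gj <- (apos - 1L) * K + wk
    gx <- rep(1, n)
    if (model$include_ige) {
      cell <- split(seq_len(n), paste(records$group, wk))
      tri <- lapply(cell, function(rows) {
        m <- length(rows)
        if (m < 2L) return(NULL)
        focal <- rep(rows, each = m - 1L)
        mate <- rep(rows, times = m)[rep(seq_len(m), each = m) != rep(seq_len(m), times = m)]
        cbind(focal, (apos[mate] - 1L) * K + J + wk[mate])
      })
      tri <- do.call(rbind, tri)
      if (!is.null(tri)) {
        gi <- c(gi, tri[, 1]); gj <- c(gj, tri[, 2]); gx <- c(gx, rep(1, nrow(tri)))
      }
    }
    Zg <- Matrix::sparseMatrix(i = gi, j = gj, x = gx, dims = c(n, nA * K))
    blocks <- c(blocks, list(Zg))
    offsets <- c(offsets, genetic = qtot)
    qtot <- qtot + nA * K
  }

  lit_ids <- grp_ids <- NULL
  if (!is.null(model$litter)) {
    lit_ids <- sort(unique(as.character(records$litter)))
    li <- match(as.character(records$litter), lit_ids)
    Zl <- Matrix::sparseMatrix(i = seq_len(n), j = (li - 1L) * J + wk,
                               dims = c(n, length(lit_ids) * J))
    blocks <- c(blocks, list(Zl))
    offsets <- c(offsets, litter = qtot)
    qtot <- qtot + length(lit_ids) * J
  }
  grp_ids <- sort(unique(as.character(records$group)))
  gri <- match(as.character(records$group), grp_ids)
  Zgr <- Matrix::sparseMatrix(i = seq_len(n), j = (gri - 1L) * J + wk,
                              dims = c(n, length(grp_ids) * J))
  blocks <- c(blocks, list(Zgr))
  offsets <- c(offsets, group = qtot)
  qtot <- qtot + length(grp_ids) * J

  W <- do.call(cbind, blocks)

  # week-pattern precomputation for the permanent-effect (residual) blocks:
  # animals grouped by their set of observed weeks; for each pattern and
  # week pair the fixed cross-products W_s'W_t, W_s'y_t, y_s'y_t are stored
  # so each likelihood evaluation is a linear combination of them.
  anim_rows <- split(seq_len(n), apos[seq_len(n)])
  pat_key <- vapply(anim_rows, function(r) paste(wk[r], collapse = ","), "")
  patterns <- list()
  for (pk in unique(pat_key)) {
    rows_by_anim <- anim_rows[pat_key == pk]
    obs <- as.integer(strsplit(pk, ",")[[1]])
    m <- length(obs)
    rows_mat <- do.call(rbind, rows_by_anim)  # animals x weeks (sorted weeks)
    terms <- list()
    for (s in seq_len(m)) {
      for (t in s:m) {
        rs <- rows_mat[, s]; rt <- rows_mat[, t]
        Ws <- W[rs, , drop = FALSE]; Wt <- W[rt, , drop = FALSE]
        M <- Matrix::crossprod(Ws, Wt)
        if (t > s) {
          S <- M + Matrix::t(M)
          v <- as.numeric(Matrix::crossprod(Ws, y[rt])) +
               as.numeric(Matrix::crossprod(Wt, y[rs]))
          q <- 2 * sum(y[rs] * y[rt])
        } else {
          S <- Matrix::forceSymmetric(M)
          v <- as.numeric(Matrix::crossprod(Ws, y[rs]))
          q <- sum(y[rs]^2)
        }
        terms[[length(terms) + 1L]] <- list(s = obs[s], t = obs[t],
                                            S = S, v = v, q = q)
      }
    }
    patterns[[length(patterns) + 1L]] <-
      list(obs = obs, n_anim = length(rows_by_anim), terms = terms)
  }

  Ainv <- if (!is.null(model$genetic)) build_A_inverse(ped) else NULL

  env <- new.env(parent = emptyenv())
  env$model <- model
  env$records <- records
  env$y <- y
  env$X <- X
  env$W <- W
  env$n <- n
  env$p <- p
  env$J <- J
  env$K <- K
  env$nA <- nA
  env$ped <- ped
  env$Ainv <- Ainv
  env$logdet_A <- attr(Ainv, "logdet_A") %||% 0
  env$offsets <- offsets
  env$n_litter <- length(lit_ids)
  env$lit_ids <- lit_ids
  env$n_group <- length(grp_ids)
  env$grp_ids <- grp_ids
  env$patterns <- patterns
  env$chol <- NULL
  class(env) <- "sad_design"
  env
}

#' @export
print.sad_design <- function(x, ...) {
  cat(sprintf("<sad_design: %d records, %d animals in pedigree, %d groups, %d parameters>\n",
              x$n, x$nA, x$n_group, n_params(x$model)))
  invisible(x)
}

# --- fast MME assembly -------------------------------------------------------
# The coefficient matrix C has a fixed sparsity pattern across likelihood
# evaluations: only its values change with omega. The cache below stores a
# template dsCMatrix plus, for every additive piece (week-pair
# cross-products, the A-inverse x Sigma_GE-inverse Kronecker block, the
# identity Kronecker blocks of litter and group), an index map into the
# template's value slot, so each evaluation is a handful of vectorized
# fills followed by a numeric Cholesky update.

lower_triplets <- function(M, di = 0L, dj = 0L) {
  T <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
  i <- T@i + 1L + di
  j <- T@j + 1L + dj
  keep <- i >= j
  list(i = i[keep], j = j[keep], x = T@x[keep])
}

build_mme_cache <- function(design) {
  K <- design$K
  J <- design$J
  p <- design$p

  pieces <- list()
  # week-pair cross-product terms (values fixed, coefficient from Sigma_p)
  for (g in seq_along(design$patterns)) {
    pat <- design$patterns[[g]]
    for (t in seq_along(pat$terms)) {
      tr <- lower_triplets(pat$terms[[t]]$S)
      pieces[[length(pieces) + 1L]] <-
        list(kind = "S", g = g, t = t, i = tr$i, j = tr$j, x = tr$x)
    }
  }
  if (!is.null(design$model$genetic)) {
    # genetic block: kron(Ainv, Sigma_GE^-1), offset p; both orientations
    # of Ainv are needed before expanding to K x K blocks
    Tg <- methods::as(methods::as(design$Ainv, "generalMatrix"), "TsparseMatrix")
    a_i <- Tg@i + 1L; a_j <- Tg@j + 1L; a_x <- Tg@x
    nn <- length(a_x)
    tt <- rep(seq_len(K), times = K)
    uu <- rep(seq_len(K), each = K)
    ii <- rep((a_i - 1L) * K, each = K * K) + rep(tt, nn) + p
    jj <- rep((a_j - 1L) * K, each = K * K) + rep(uu, nn) + p
    gi <- rep((uu - 1L) * K + tt, nn)     # index into vec(Sigma_inv)
    wa <- rep(a_x, each = K * K)
    keep <- ii >= jj
    pieces[[length(pieces) + 1L]] <- list(kind = "kron_gen", i = ii[keep],
                                          j = jj[keep], w = wa[keep],
                                          gi = gi[keep])
  }
  # identity-kron blocks (litter, group)
  id_block <- function(nblk, off, kind) {
    tt <- rep(seq_len(J), times = J)
    uu <- rep(seq_len(J), each = J)
    keep0 <- tt >= uu
    tt <- tt[keep0]; uu <- uu[keep0]
    m <- length(tt)
    blk <- rep(seq_len(nblk) - 1L, each = m) * J
    list(kind = kind,
         i = rep(tt, nblk) + blk + off,
         j = rep(uu, nblk) + blk + off,
         gi = rep((uu - 1L) * J + tt, nblk))
  }
  if (!is.null(design$model$litter)) {
    pieces[[length(pieces) + 1L]] <-
      id_block(design$n_litter, design$offsets[["litter"]], "kron_litter")
  }
  pieces[[length(pieces) + 1L]] <-
    id_block(design$n_group, design$offsets[["group"]], "kron_group")

  all_i <- unlist(lapply(pieces, `[[`, "i"))
  all_j <- unlist(lapply(pieces, `[[`, "j"))
  ntot <- ncol(design$W)
  tmpl <- Matrix::sparseMatrix(i = all_i, j = all_j, x = 1,
                               dims = c(ntot, ntot))
  tmpl <- Matrix::forceSymmetric(tmpl, "L")
  Tt <- methods::as(tmpl, "TsparseMatrix")
  key_tmpl <- as.double(Tt@j) * ntot + as.double(Tt@i)
  for (k in seq_along(pieces)) {
    pc <- pieces[[k]]
    key <- as.double(pc$j - 1L) * ntot + as.double(pc$i - 1L)
    pieces[[k]]$map <- match(key, key_tmpl)
    pieces[[k]]$i <- pieces[[k]]$j <- NULL
  }
  list(tmpl = tmpl, pieces = pieces, nnz = length(tmpl@x), ntot = ntot)
}

# Assemble MME pieces at parameters omega. Returns NULL on numerical
# failure (treated as -Inf likelihood by callers).
mme_pieces <- function(design, omega) {
  model <- set_params(design$model, omega)
  grid <- model$grid
  J <- design$J
  if (is.null(design$cache)) design$cache <- build_mme_cache(design)
  cache <- design$cache

  chol_inv <- function(sig) {
    ch <- tryCatch(chol(sig), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    list(inv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
  }

  sig_p <- sad_sigma(model$permanent, grid)
  logdetR <- 0
  rcoef <- vector("list", length(design$patterns))
  v_sum <- 0
  q_sum <- 0
  for (g in seq_along(design$patterns)) {
    pat <- design$patterns[[g]]
    ci <- chol_inv(sig_p[pat$obs, pat$obs, drop = FALSE])
    if (is.null(ci)) return(NULL)
    logdetR <- logdetR + pat$n_anim * ci$logdet
    rc <- numeric(length(pat$terms))
    for (t in seq_along(pat$terms)) {
      tm <- pat$terms[[t]]
      r <- ci$inv[match(tm$s, pat$obs), match(tm$t, pat$obs)]
      rc[t] <- r
      v_sum <- v_sum + r * tm$v
      q_sum <- q_sum + r * tm$q
    }
    rcoef[[g]] <- rc
  }

  ge <- NULL
  logdetG <- 0
  if (!is.null(model$genetic)) {
    ge <- chol_inv(sad_sigma(model$genetic, grid))
    if (is.null(ge)) return(NULL)
    logdetG <- design$K * design$logdet_A + design$nA * ge$logdet
  }
  lt <- NULL
  if (!is.null(model$litter)) {
    lt <- chol_inv(sad_sigma(model$litter, grid))
    if (is.null(lt)) return(NULL)
    logdetG <- logdetG + design$n_litter * lt$logdet
  }
  gr <- chol_inv(sad_sigma(model$group, grid))
  if (is.null(gr)) return(NULL)
  logdetG <- logdetG + design$n_group * gr$logdet

  ge_vec <- if (!is.null(ge)) as.vector(ge$inv) else NULL
  gr_vec <- as.vector(gr$inv)
  lt_vec <- if (!is.null(lt)) as.vector(lt$inv) else NULL

  xacc <- numeric(cache$nnz)
  for (pc in cache$pieces) {
    vals <- switch(pc$kind,
      S = rcoef[[pc$g]][pc$t] * pc$x,
      kron_gen = pc$w * ge_vec[pc$gi],
      kron_litter = lt_vec[pc$gi],
      kron_group = gr_vec[pc$gi])
    xacc[pc$map] <- xacc[pc$map] + vals
  }
  C <- cache$tmpl
  C@x <- xacc
  list(C = C, rhs = v_sum, yry = q_sum,
       logdetR = logdetR, logdetG = logdetG, model = model)
}

design_chol <- function(design, C) {
  ch <- NULL
  if (!is.null(design$chol)) {
    ch <- tryCatch(Matrix::update(design$chol, C), error = function(e) NULL)
  }
  if (is.null(ch)) {
    ch <- tryCatch(Matrix::Cholesky(C, LDL = FALSE, super = TRUE),
                   error = function(e) NULL)
    if (!is.null(ch)) design$chol <- ch
  }
  ch
}

#' Restricted log-likelihood of the residual-free SAD model
#'
#' Computed through the sparse mixed-model-equations identities
#' \eqn{\log|V| + \log|X'V^{-1}X| = \log|R| + \log|G| + \log|C|} and
#' \eqn{y'Py = y'R^{-1}y - \hat\theta' W'R^{-1}y}, never forming the dense
#' phenotypic covariance V. Includes the \eqn{-(n-p)/2 \log 2\pi} constant.
#'
#' @param omega Packed parameter vector (see [pack_params()]).
#' @param design A [build_design()] object.
#' @return Restricted log-likelihood (scalar; `-Inf` if `omega` yields a
#'   numerically invalid covariance).
#' @export
reml_loglik <- function(omega, design) {
  pieces <- tryCatch(mme_pieces(design, omega), error = function(e) NULL)
  if (is.null(pieces)) return(-Inf)
  ch <- design_chol(design, pieces$C)
  if (is.null(ch)) return(-Inf)
  logdetC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  sol <- Matrix::solve(ch, pieces$rhs, system = "A")
  yPy <- pieces$yry - sum(as.numeric(sol) * pieces$rhs)
  ll <- -0.5 * (pieces$logdetR + pieces$logdetG + logdetC + yPy +
                (design$n - design$p) * log(2 * pi))
  if (!is.finite(ll)) return(-Inf)
  ll
}

# Data-driven starting values: split the per-week phenotypic variance of
# fixed-effect residuals into fixed shares, convert each share to SAD
# parameters (flat theta, log-linear innovation variance fitted by least
# squares). Truth-independent.
default_start <- function(design) {
  model <- design$model
  w <- grid_points(model$grid)
  res <- stats::residuals(stats::lm(design$y ~ design$X - 1))
  wkpos <- match(design$records$week, model$grid$weeks)
  v_week <- tapply(res, wkpos, stats::var)
  v <- rep(mean(v_week, na.rm = TRUE), design$J)
  v[as.integer(names(v_week))] <- v_week
  v <- pmax(v, 1e-3)

  share <- c(genetic = 0.2, ige = 0.01, litter = 0.1, group = 0.15,
             permanent = 0.5)
  theta0 <- 0.3
  logvar_coefs <- function(target, fn) {
    lv <- log(pmax(target * (1 - theta0^2), 1e-6))
    deg <- fn$degree
    stats::lm.fit(outer(w, 0:deg, `^`), lv)$coefficients
  }
  start_spec <- function(spec, target) {
    for (s in seq_along(spec$antedependence)) {
      cf <- numeric(spec$antedependence[[s]]$degree + 1L)
      cf[1] <- if (s == 1L) theta0 else 0
      spec$antedependence[[s]] <- poly_fn(cf)
    }
    spec$innovation_logvar <- poly_fn(logvar_coefs(target, spec$innovation_logvar))
    spec
  }
  if (model$include_ige) {
    gen <- model$genetic
    gen$primary <- start_spec(gen$primary, share["genetic"] * v)
    gen$secondary <- start_spec(gen$secondary, share["ige"] * v)
    gen$cross <- poly_fn(numeric(gen$cross$degree + 1L))
    model$genetic <- gen
  } else if (!is.null(model$genetic)) {
    model$genetic <- start_spec(model$genetic, share["genetic"] * v)
  }
  if (!is.null(model$litter)) model$litter <- start_spec(model$litter, share["litter"] * v)
  model$group <- start_spec(model$group, share["group"] * v)
  model$permanent <- start_spec(model$permanent, share["permanent"] * v)
  pack_params(model)
}

#' SAD parameter approximation of given covariance matrices
#'
#' Converts per-effect covariance matrices into the packed parameter
#' vector of a model by sequential-regression decomposition: each matrix
#' is refactored into antedependence coefficients and innovation variances
#' ([sad_decompose()]), restricted to the model's lags (for the correlated
#' genetic pair, the direct effect is regressed on its own lags and the
#' same-week indirect value), and the resulting week series are projected
#' onto the model's polynomial degrees by least squares. Useful as a
#' starting value for [fit_reml()] when plausible covariance values are
#' available (e.g. literature estimates, or the generating values of a
#' simulation study).
#'
#' @param model A [sad_model()].
#' @param sigma Named list of covariance matrices: `genetic` (2J x 2J,
#'   DGE block first, when the model includes IGE; J x J otherwise),
#'   `group`, `permanent`, and `litter` if modelled.
#' @return Packed parameter vector (see [pack_params()]).
#' @export
approx_sad_params <- function(model, sigma) {
  w <- grid_points(model$grid)
  J <- length(w)
  project <- function(series, idx, degree) {
    X <- outer(w[idx], 0:degree, `^`)
    cf <- stats::lm.fit(X, series[idx])$coefficients
    cf[is.na(cf)] <- 0
    unname(cf)
  }
  fit_single <- function(spec, S) {
    dec <- sad_decompose(S)
    for (s in seq_along(spec$antedependence)) {
      idx <- (s + 1):J
      spec$antedependence[[s]] <-
        poly_fn(project(dec$theta[, s], idx, spec$antedependence[[s]]$degree))
    }
    spec$innovation_logvar <-
      poly_fn(project(log(pmax(dec$d, 1e-8)), 1:J,
                      spec$innovation_logvar$degree))
    spec
  }
  if (model$include_ige) {
    Sg <- sigma$genetic
    gen <- model$genetic
    gen$secondary <- fit_single(gen$secondary, Sg[J + 1:J, J + 1:J])
    alpha <- gen$primary$order
    thD <- matrix(0, J, max(alpha, 1L))
    deltas <- dD <- numeric(J)
    for (j in 1:J) {
      lags <- j - seq_len(min(alpha, j - 1L))
      preds <- c(lags, J + j)   # own lags, then same-week IGE
      B <- solve(Sg[preds, preds], Sg[preds, j])
      if (length(lags)) thD[j, seq_along(lags)] <- B[seq_along(lags)]
      deltas[j] <- B[length(B)]
      dD[j] <- Sg[j, j] - sum(B * Sg[preds, j])
    }
    for (s in seq_len(alpha)) {
      gen$primary$antedependence[[s]] <-
        poly_fn(project(thD[, s], (s + 1):J,
                        gen$primary$antedependence[[s]]$degree))
    }
    gen$primary$innovation_logvar <-
      poly_fn(project(log(pmax(dD, 1e-8)), 1:J,
                      gen$primary$innovation_logvar$degree))
    gen$cross <- poly_fn(project(deltas, 1:J, gen$cross$degree))
    model$genetic <- gen
  } else if (!is.null(model$genetic)) {
    model$genetic <- fit_single(model$genetic, sigma$genetic)
  }
  if (!is.null(model$litter)) model$litter <- fit_single(model$litter, sigma$litter)
  model$group <- fit_single(model$group, sigma$group)
  model$permanent <- fit_single(model$permanent, sigma$permanent)
  pack_params(model)
}

# Drop every polynomial to degree 0 (constant), keeping SAD orders: the
# first rung of the warm-start ladder.
reduce_to_constant <- function(model) {
  red_fn <- function(fn) poly_fn(fn$coefficients[1])
  red_spec <- function(spec) {
    spec$antedependence <- lapply(spec$antedependence, red_fn)
    spec$innovation_logvar <- red_fn(spec$innovation_logvar)
    spec
  }
  if (model$include_ige) {
    model$genetic$primary <- red_spec(model$genetic$primary)
    model$genetic$secondary <- red_spec(model$genetic$secondary)
    model$genetic$cross <- red_fn(model$genetic$cross)
  } else if (!is.null(model$genetic)) {
    model$genetic <- red_spec(model$genetic)
  }
  if (!is.null(model$litter)) model$litter <- red_spec(model$litter)
  model$group <- red_spec(model$group)
  model$permanent <- red_spec(model$permanent)
  model
}

# Zero-pad constant-model estimates back to the full model's packing.
expand_params <- function(full_model, const_model) {
  omega_c <- pack_params(const_model)
  om <- pack_params(full_model)
  om[] <- 0
  # walk both packings in parallel: every polynomial's constant term comes
  # from the constant model, higher-order terms start at zero
  full_lens <- poly_lengths(full_model)
  i_full <- 1L
  i_const <- 1L
  for (len in full_lens) {
    om[i_full] <- omega_c[i_const]
    i_full <- i_full + len
    i_const <- i_const + 1L
  }
  om
}

poly_lengths <- function(model) {
  lens <- integer(0)
  spec_lens <- function(spec) {
    if (inherits(spec, "cross_sad_spec")) {
      c(vapply(spec$primary$antedependence, function(f) f$degree + 1L, 0L),
        vapply(spec$secondary$antedependence, function(f) f$degree + 1L, 0L),
        spec$cross$degree + 1L,
        spec$primary$innovation_logvar$degree + 1L,
        spec$secondary$innovation_logvar$degree + 1L)
    } else {
      c(vapply(spec$antedependence, function(f) f$degree + 1L, 0L),
        spec$innovation_logvar$degree + 1L)
    }
  }
  for (term in model_terms(model)) lens <- c(lens, spec_lens(term))
  lens
}

#' Fit the SAD mixed model by REML
#'
#' Maximizes the restricted likelihood over the packed polynomial
#' parameters with a finite-difference quasi-Newton search (L-BFGS-B),
#' optionally preceded by a warm-start ladder: all parameter functions are
#' first reduced to constants (degree 0), fitted, and the estimates used as
#' starting values for the full-degree model. Convergence is the
#' optimizer's own criterion on the relative log-likelihood change.
#'
#' @param design A [build_design()] object, or a phenotype data frame (in
#'   which case `model` and `ped` must be supplied).
#' @param model,ped Used only when `design` is a data frame.
#' @param init Numeric starting vector, `"ladder"` (default) for the
#'   warm-start ladder, or `"direct"` for the data-driven start alone.
#' @param maxit Maximum quasi-Newton iterations for the main stage.
#' @param factr L-BFGS-B convergence factor (see [stats::optim()]); the
#'   default stops when the restricted log-likelihood changes by less than
#'   about 1e-6 in relative terms.
#' @return An object of class `sad_fit`: estimates (`omega`, and the model
#'   with estimates substituted), `loglik`, `convergence` flag, per-effect
#'   covariance matrices (`sigma`), and bookkeeping.
#' @export
fit_reml <- function(design, model = NULL, ped = NULL, init = "ladder",
                     maxit = 150, factr = 1e9) {
  if (is.data.frame(design)) {
    stopifnot(!is.null(model))
    design <- build_design(design, model, ped)
  }
  model <- design$model
  negll <- function(om) {
    ll <- reml_loglik(om, design)
    if (!is.finite(ll)) 1e10 else -ll
  }
  lbfgs <- function(fn, start, maxit) {
    stats::optim(start, fn, method = "L-BFGS-B",
                 control = list(maxit = maxit, factr = factr,
                                ndeps = rep(1e-5, length(start))))
  }

  if (is.numeric(init)) {
    start <- init
  } else if (identical(init, "ladder") && any(poly_lengths(model) > 1L)) {
    # first rung: all parameter functions constant (degree 0); a coarse
    # stopping factor suffices for a starting value
    const_model <- reduce_to_constant(model)
    cdesign <- build_design(design$records, const_model, design$ped)
    cstart <- default_start(cdesign)
    cfit <- stats::optim(cstart, function(om) {
      ll <- reml_loglik(om, cdesign)
      if (!is.finite(ll)) 1e10 else -ll
    }, method = "L-BFGS-B",
    control = list(maxit = maxit, factr = max(factr, 1e10),
                   ndeps = rep(1e-5, length(cstart))))
    start <- expand_params(model, set_params(const_model, cfit$par))
  } else {
    start <- default_start(design)
  }

  if (maxit == 0) {
    # evaluation at fixed parameters (e.g. reloading a stored fit)
    opt <- list(par = start, value = negll(start), convergence = 0L,
                counts = c(1L, 0L))
  } else {
    opt <- lbfgs(negll, start, maxit)
  }
  converged <- opt$convergence == 0 && opt$value < 1e9

  est_model <- set_params(model, opt$par)
  grid <- model$grid
  sigma <- list(group = sad_sigma(est_model$group, grid),
                permanent = sad_sigma(est_model$permanent, grid))
  if (!is.null(est_model$genetic)) {
    sigma <- c(list(genetic = sad_sigma(est_model$genetic, grid)), sigma)
  }
  if (!is.null(est_model$litter)) sigma$litter <- sad_sigma(est_model$litter, grid)

  structure(list(omega = opt$par, model = est_model, loglik = -opt$value,
                 convergence = converged, optim = opt[c("convergence", "counts")],
                 n_params = length(opt$par), sigma = sigma,
                 design = design),
            class = "sad_fit")
}

#' @export
print.sad_fit <- function(x, ...) {
  cat(sprintf("<sad_fit: logLik %.3f, %d parameters, %s>\n", x$loglik,
              x$n_params, if (x$convergence) "converged" else "NOT converged"))
  invisible(x)
}

#' Likelihood-ratio test between nested SAD model fits
#'
#' @param fit_full,fit_reduced [fit_reml()] results on the same data; the
#'   reduced model's parameters must be a constrained subset of the full
#'   model's.
#' @param tol Negative statistics smaller than `-tol` raise a
#'   convergence-failure error.
#' @return List with `statistic`, `df` (literal free-parameter-count
#'   difference) and `p_value`.
#' @export
lrt <- function(fit_full, fit_reduced, tol = 1e-6) {
  stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
  df <- fit_full$n_params - fit_reduced$n_params
  if (df < 0) stopf("reduced model has more parameters than full model")
  if (stat < -tol) {
    stopf("negative LRT statistic (%.4g): a fit failed to converge", stat)
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_)
}

#' Observed information matrix by central finite differences
#'
#' Central second differences of the restricted log-likelihood at the
#' estimates, with relative step `h`. Returns the information matrix
#' I(omega-hat) = -Hessian and its inverse H (the sampling covariance used
#' by [mvn_sampling_se()]), symmetrized.
#'
#' @param fit A [fit_reml()] result.
#' @param h Relative finite-difference step.
#' @return List with `info`, `H` (inverse information) and `omega`.
#' @export
reml_info <- function(fit, h = 1e-4) {
  design <- fit$design
  om <- fit$omega
  k <- length(om)
  step <- h * pmax(abs(om), 1)
  f0 <- reml_loglik(om, design)
  Hmat <- matrix(0, k, k)
  fp <- fm <- numeric(k)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- step[i]
    fp[i] <- reml_loglik(om + ei, design)
    fm[i] <- reml_loglik(om - ei, design)
    Hmat[i, i] <- (fp[i] - 2 * f0 + fm[i]) / step[i]^2
  }
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        ei <- numeric(k); ei[i] <- step[i]
        ej <- numeric(k); ej[j] <- step[j]
        fpp <- reml_loglik(om + ei + ej, design)
        fpm <- reml_loglik(om + ei - ej, design)
        fmp <- reml_loglik(om - ei + ej, design)
        fmm <- reml_loglik(om - ei - ej, design)
        Hmat[i, j] <- Hmat[j, i] <- (fpp - fpm - fmp + fmm) / (4 * step[i] * step[j])
      }
    }
  }
  info <- symmetrize(-Hmat)
  Hinv <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(Hinv)) {
    # ridge fallback for near-singular information
    Hinv <- solve(info + diag(1e-8 * max(abs(diag(info))), k))
  }
  list(info = info, H = symmetrize(Hinv), omega = om)
}

#' Identifiability diagnostics of a fitted model
#'
#' Condition number (square root of the ratio of the largest to the
#' smallest eigenvalue) of the information matrix, optionally of a
#' submatrix, and the correlation matrix of the parameter estimates derived
#' from the inverse information.
#'
#' @param info A [reml_info()] result (or a list with elements `info`, `H`).
#' @param subset Optional integer indices selecting an information
#'   submatrix for a second condition number.
#' @return List with `condition`, `condition_subset` (or `NA`),
#'   `param_correlations`, and a `psd` flag for the information matrix.
#' @export
identifiability_diagnostics <- function(info, subset = NULL) {
  I <- info$info
  ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  psd <- min(ev) > -1e-8 * max(abs(ev))
  cond <- if (min(ev) > 0) sqrt(max(ev) / min(ev)) else Inf
  cond_sub <- NA_real_
  if (!is.null(subset)) {
    evs <- eigen(I[subset, subset, drop = FALSE], symmetric = TRUE,
                 only.values = TRUE)$values
    cond_sub <- if (min(evs) > 0) sqrt(max(evs) / min(evs)) else Inf
  }
  H <- info$H
  corr <- stats::cov2cor(H)
  list(condition = cond, condition_subset = cond_sub,
       param_correlations = corr, psd = psd)
}
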