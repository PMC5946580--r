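# Independent oracles and small-data builders shared across tests.

# Dense-matrix restricted log-likelihood: forms the full phenotypic
# covariance V = sum_e Z_e (K_e x Sigma_e) Z_e' + R and evaluates
# -1/2 [log|V| + log|X'V^-1 X| + y'Py] - (n-p)/2 log 2pi directly.
# Deliberately independent of the package's sparse MME path.
dense_reml_oracle <- function(design, omega) {
  model <- sadige::set_params(design$model, omega)
  grid <- model$grid
  J <- design$J
  W <- as.matrix(design$W)
  p <- design$p
  X <- W[, seq_len(p), drop = FALSE]
  n <- design$n
  V <- matrix(0, n, n)
  if (!is.null(model$genetic)) {
    A <- sadige::build_A(design$ped)
    sig_ge <- sadige::sad_sigma(model$genetic, grid)
    Zg <- W[, design$offsets[["genetic"]] + seq_len(design$nA * design$K),
            drop = FALSE]
    V <- V + Zg %*% kronecker(A, sig_ge) %*% t(Zg)
  }
  if (!is.null(model$litter)) {
    Zl <- W[, design$offsets[["litter"]] + seq_len(design$n_litter * J),
            drop = FALSE]
    V <- V + Zl %*% kronecker(diag(design$n_litter),
                              sadige::sad_sigma(model$litter, grid)) %*% t(Zl)
  }
  Zr <- W[, design$offsets[["group"]] + seq_len(design$n_group * J),
          drop = FALSE]
  V <- V + Zr %*% kronecker(diag(design$n_group),
                            sadige::sad_sigma(model$group, grid)) %*% t(Zr)
  sig_p <- sadige::sad_sigma(model$permanent, grid)
  wk <- match(design$records$week, grid$weeks)
  anim <- design$records$animal
  for (a in unique(anim)) {
    rows <- which(anim == a)
    V[rows, rows] <- V[rows, rows] + sig_p[wk[rows], wk[rows]]
  }
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
  y <- design$y
  ll <- -0.5 * (as.numeric(determinant(V)$modulus) +
                as.numeric(determinant(XVX)$modulus) +
                drop(t(y) %*% P %*% y) + (n - p) * log(2 * pi))
  beta <- drop(solve(XVX, t(X) %*% Vi %*% y))
  u_g <- NULL
  if (!is.null(model$genetic)) {
    u_g <- drop(kronecker(A, sig_ge) %*% t(Zg) %*% P %*% y)
  }
  list(ll = ll, beta = beta, u_g = u_g)
}

# Small social dataset: n_cages cages of `cage_size` offspring from a
# two-generation pedigree, J weeks, optional litters.
make_social_data <- function(n_cages = 3, cage_size = 8, J = 2,
                             litters = TRUE, drop_record = TRUE, seed = 42) {
  withr::with_seed(seed, {
    n_off <- n_cages * cage_size
    n_sires <- max(2, n_off %/% 6)
    n_dams <- max(3, n_off %/% 4)
    sires <- paste0("s", seq_len(n_sires))
    dams <- paste0("d", seq_len(n_dams))
    off <- paste0("k", seq_len(n_off))
    lit <- sample(n_dams, n_off, replace = TRUE)
    ped <- sadige::pedigree(c(sires, dams, off),
                            c(rep(0, n_sires + n_dams),
                              sires[((lit - 1) %% n_sires) + 1]),
                            c(rep(0, n_sires + n_dams), dams[lit]))
    records <- expand.grid(animal = off, week = seq_len(J),
                           stringsAsFactors = FALSE)
    records$group <- rep(rep(seq_len(n_cages), each = cage_size), J)
    if (litters) records$litter <- rep(lit, J)
    records$adg <- rnorm(nrow(records), 30, 5)
    if (drop_record) records <- records[-2, , drop = FALSE]
    list(ped = ped, records = records)
  })
}

rand_poly <- function(max_deg, scale = 0.3) {
  deg <- sample(0:max_deg, 1)
  sadige::poly_fn(runif(deg + 1, -scale, scale))
}

rand_sad_spec <- function(max_order = 2, max_deg = 2) {
  order <- sample(0:max_order, 1)
  sadige::sad_spec(replicate(order, rand_poly(max_deg), simplify = FALSE),
                   sadige::poly_fn(runif(sample(0:max_deg, 1) + 1, -0.4, 0.4)))
}

rand_model <- function(J = 2, litter = TRUE, ige = TRUE) {
  s11 <- function() sadige::sad_spec(list(rand_poly(1)), rand_poly(1, 0.5))
  genetic <- if (ige) {
    sadige::cross_sad_spec(s11(), s11(), rand_poly(1, 0.4))
  } else {
    s11()
  }
  sadige::sad_model(genetic = genetic, group = s11(), permanent = s11(),
                    litter = if (litter) s11(),
                    fixed = if (J > 1) ~ 0 + factor(week) else ~ 1,
                    grid = sadige::time_grid(seq_len(J)))
}

# Gene-dropping estimate of the additive relationship matrix: founders get
# unique alleles, descendants inherit one random allele per parent;
# A_ij = 2 * P(randomly drawn alleles are identical by descent).
gene_drop_A <- function(ped, n_drops = 1e5) {
  n <- nrow(ped)
  a1 <- matrix(0L, n_drops, n)
  a2 <- matrix(0L, n_drops, n)
  next_allele <- 1L
  for (i in seq_len(n)) {
    s <- ped$si[i]; d <- ped$di[i]
    if (s > 0L) {
      pick <- runif(n_drops) < 0.5
      a1[, i] <- ifelse(pick, a1[, s], a2[, s])
    } else {
      a1[, i] <- next_allele; next_allele <- next_allele + 1L
    }
    if (d > 0L) {
      pick <- runif(n_drops) < 0.5
      a2[, i] <- ifelse(pick, a1[, d], a2[, d])
    } else {
      a2[, i] <- next_allele; next_allele <- next_allele + 1L
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- (a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
             (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])
      A[i, j] <- A[j, i] <- 2 * mean(ibd) / 4
    }
  }
  A
}
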