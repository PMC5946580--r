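# Default simulation parameters.
#
# The study conditions are unstructured per-week covariance matrices close
# to the SAD estimates for restricted-fed growing rabbits: direct genetic
# variance rising from ~8 to ~13.5 (g/d)^2 and falling to ~6.2 by week 5,
# small indirect genetic variances (~0.2-0.45), group variance rising from
# ~5.7 to ~16.4, pseudo-permanent variance from ~23 to ~53, litter variance
# falling from ~8.7 to ~4.2, and a strong direct-indirect genetic
# antagonism (within-week correlations around -0.6 to -0.8). Correlation
# values between the printed anchors are mid-range interpolations; the
# matrices are synthetic approximations, not published estimates.
#
# The joint genetic correlation matrix is built as
# [[R_D, -L_D K L_I'], [., R_I]] with L the Cholesky factors of the two
# marginal correlation matrices and K a fixed 5 x 5 coupling matrix with
# largest singular value < 1; the Schur complement of the joint matrix is
# then R_I - L_I K'K L_I' >= (1 - sigma_max(K)^2) R_I > 0, so the
# construction is positive definite by design. K was calibrated once so
# the strong-antagonism set shows within-week direct-indirect correlations
# near -0.73, negative between-week cross correlations, total-breeding-
# value correlations of week 1 with weeks 2-5 of about (-0.30, -0.07,
# 0.00, 0.05), and a near-zero covariance between the direct-EBV-sum
# criterion and the total breeding value sum.

toeplitz_corr <- function(lags) {
  J <- length(lags)
  outer(seq_len(J), seq_len(J), function(i, j) lags[abs(i - j) + 1L])
}

#' Default genetic covariance matrix for the selection simulation
#'
#' 10 x 10 covariance of direct (weeks 1-5) and indirect (weeks 1-5)
#' genetic effects. The `antagonism` level rescales the direct-indirect
#' cross-covariance block: `strong` keeps it, `moderate` halves it, `weak`
#' quarters it; the rescaling is a convex combination with the
#' block-diagonal matrix and therefore preserves positive semi-definiteness
#' (verified).
#'
#' @param antagonism `"strong"`, `"moderate"` or `"weak"`.
#' @return 10 x 10 covariance matrix, DGE block first.
#' @export
default_genetic_covariance <- function(antagonism = c("strong", "moderate", "weak")) {
  antagonism <- match.arg(antagonism)
  R_D <- toeplitz_corr(c(1, 0.86, 0.75, 0.60, 0.46))
  R_I <- toeplitz_corr(c(1, 0.91, 0.75, 0.62, 0.50))
  R_I[1, 2:5] <- c(0.47, 0.42, 0.37, 0.33)
  R_I[2:5, 1] <- R_I[1, 2:5]
  K <- matrix(c(0.7248, 0.3099, -0.3899, -0.1145, 0.0718,
                0.3703, 0.1884, 0.3613, 0.2054, 0.0481,
                0.2770, -0.5816, 0.5199, 0.1573, 0.0977,
                -0.0986, 0.2831, 0.2184, 0.3201, 0.2316,
                0.0306, 0.0532, 0.0369, 0.0685, 0.0429), 5, 5)
  B <- -t(chol(R_D)) %*% K %*% chol(R_I)
  joint <- rbind(cbind(R_D, B), cbind(t(B), R_I))
  s <- sqrt(c(8.03, 11.0, 13.47, 10.0, 6.20,
              0.44, 0.35, 0.28, 0.22, 0.31))
  sigma <- diag(s) %*% joint %*% diag(s)
  div <- c(strong = 1, moderate = 2, weak = 4)[[antagonism]]
  sigma[1:5, 6:10] <- sigma[1:5, 6:10] / div
  sigma[6:10, 1:5] <- sigma[6:10, 1:5] / div
  if (!is_psd(sigma)) stopf("antagonism rescaling broke positive definiteness")
  nm <- c(paste0("DGE.w", 1:5), paste0("IGE.w", 1:5))
  dimnames(sigma) <- list(nm, nm)
  sigma
}

#' Default group (cage) covariance matrix
#'
#' Variance rising from 5.7 to 16.4 (g/d)^2 over the five weeks, with
#' small negative correlations between consecutive weeks.
#' @export
default_group_covariance <- function() {
  v <- c(5.7, 7.7, 10.2, 13.1, 16.4)
  corr <- toeplitz_corr(c(1, -0.23, 0, 0, 0))
  sigma <- diag(sqrt(v)) %*% corr %*% diag(sqrt(v))
  dimnames(sigma) <- list(paste0("w", 1:5), paste0("w", 1:5))
  sigma
}

#' Default pseudo-permanent covariance matrix
#'
#' Variance rising from 23.1 to 52.8 (g/d)^2; weak negative correlations
#' between consecutive weeks from week 2 onward. Because the model carries
#' no separate residual, this matrix also plays the residual's role.
#' @export
default_permanent_covariance <- function() {
  v <- c(23.1, 28.7, 35.5, 43.9, 52.8)
  corr <- diag(5)
  corr[2, 3] <- corr[3, 2] <- -0.08
  corr[3, 4] <- corr[4, 3] <- -0.13
  corr[4, 5] <- corr[5, 4] <- -0.18
  sigma <- diag(sqrt(v)) %*% corr %*% diag(sqrt(v))
  dimnames(sigma) <- list(paste0("w", 1:5), paste0("w", 1:5))
  sigma
}

#' Default litter covariance matrix
#'
#' Variance falling from 8.7 to 4.2 (g/d)^2, positive correlations that
#' decay with the time interval and are weaker between week 1 and later
#' weeks (the waning maternal influence).
#' @export
default_litter_covariance <- function() {
  v <- c(8.7, 7.2, 6.0, 5.0, 4.2)
  corr <- toeplitz_corr(c(1, 0.84, 0.60, 0.37, 0.20))
  corr[1, 2:5] <- c(0.38, 0.30, 0.22, 0.14)
  corr[2:5, 1] <- corr[1, 2:5]
  sigma <- diag(sqrt(v)) %*% corr %*% diag(sqrt(v))
  dimnames(sigma) <- list(paste0("w", 1:5), paste0("w", 1:5))
  sigma
}

#' Default weekly mean average daily gain (g/d)
#' @export
default_week_means <- function() {
  c(w1 = 26.51, w2 = 37.54, w3 = 42.02, w4 = 40.11, w5 = 41.20)
}

#' Bundle of simulation truth parameters
#'
#' @param antagonism Direct-indirect genetic antagonism level.
#' @return List with elements `genetic` (10 x 10), `group`, `permanent`
#'   (5 x 5), `means` (length 5) and `antagonism`; class `sim_parameters`.
#' @export
sim_parameters <- function(antagonism = c("strong", "moderate", "weak")) {
  antagonism <- match.arg(antagonism)
  structure(list(genetic = default_genetic_covariance(antagonism),
                 group = default_group_covariance(),
                 permanent = default_permanent_covariance(),
                 means = default_week_means(),
                 antagonism = antagonism),
            class = "sim_parameters")
}
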