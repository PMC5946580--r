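test_that("total phenotypic variance implements the group-size formula", {
  only_direct <- list(dge_var = 10)
  expect_equal(total_phenotypic_variance(only_direct, 8, 0.16), 10)
  # full arithmetic at the printed coefficients (group size 8)
  cp <- list(dge_var = 8, ige_var = 0.4, dge_ige_cov = -1,
             litter_var = 8.7, group_var = 5.7, perm_var = 23.1)
  expect_equal(total_phenotypic_variance(cp, 8, 0.16), 48.748)
  # r = 0 removes the relatedness bracket entirely
  expect_equal(total_phenotypic_variance(cp, 8, 0),
               8 + 7 * 0.4 + 8.7 + 5.7 + 23.1)
  # generalized coefficients: n = 2 gives (n-1) = 1, (n-2) = 0
  expect_equal(total_phenotypic_variance(cp, 2, 0.5),
               8 + 0.4 + 0.5 * 2 * (-1) + 37.5)
})

test_that("total phenotypic variance is additive in each component", {
  withr::with_seed(3, {
    base <- list(dge_var = runif(5, 1, 10), ige_var = runif(5, 0, 1),
                 dge_ige_cov = runif(5, -1, 0), litter_var = runif(5),
                 group_var = runif(5), perm_var = runif(5, 5, 20))
    t0 <- total_phenotypic_variance(base, 8, 0.16)
    for (nm in c("dge_var", "litter_var", "group_var", "perm_var")) {
      bumped <- base
      bumped[[nm]] <- bumped[[nm]] + 1
      expect_equal(total_phenotypic_variance(bumped, 8, 0.16), t0 + 1)
    }
    doubled <- lapply(base, `*`, 2)
    expect_equal(total_phenotypic_variance(doubled, 8, 0.16), 2 * t0)
  })
})

test_that("heritabilities follow the variance-ratio definitions", {
  cp <- list(dge_var = 10, ige_var = 0, dge_ige_cov = 0,
             litter_var = 0, group_var = 5, perm_var = 25)
  h <- heritabilities(cp, 8, 0.16)
  expect_equal(h$h2_direct, h$h2_total)
  expect_equal(h$h2_indirect, 0)
  # sigma_TBV = dge + 14 cov + 49 ige collapses to zero at the quadratic root
  cp2 <- list(dge_var = 49, ige_var = 1, dge_ige_cov = -7,
              litter_var = 0, group_var = 1, perm_var = 1)
  h2 <- heritabilities(cp2, 8, 0)
  expect_equal(h2$tbv_var, 0)
  expect_equal(h2$h2_total, 0)
  expect_error(heritabilities(list(dge_var = 0, ige_var = 0, dge_ige_cov = 0,
                                   litter_var = 0, group_var = 0,
                                   perm_var = 0)),
               "non-positive")
})

test_that("component extraction matches the fitted covariance matrices", {
  m <- default_sad_model(TRUE)
  m <- set_params(m, withr::with_seed(2, rnorm(18, 0, 0.2)))
  sig <- list(genetic = sad_sigma(m$genetic, m$grid),
              group = sad_sigma(m$group, m$grid),
              permanent = sad_sigma(m$permanent, m$grid))
  cp <- variance_components(sig)
  expect_equal(cp$dge_var, unname(diag(sig$genetic)[1:5]))
  expect_equal(cp$ige_var, unname(diag(sig$genetic)[6:10]))
  expect_equal(cp$dge_ige_cov, unname(diag(sig$genetic[1:5, 6:10])))
})

make_fake_fit <- function(b0 = log(2), c0 = 0) {
  model <- sad_model(genetic = NULL,
                     group = sad_spec(list(), poly_fn(b0)),
                     permanent = sad_spec(list(), poly_fn(c0)),
                     grid = time_grid(1))
  list(model = model, omega = c(b0, c0),
       sigma = list(group = sad_sigma(model$group, model$grid),
                    permanent = sad_sigma(model$permanent, model$grid)))
}

test_that("MVN sampling reduces to the delta method on the scalar case", {
  # group variance = exp(b0) with b0 ~ N(mu, s^2): delta-method SE is
  # exp(mu) * s; the lognormal mean is exp(mu + s^2/2)
  mu <- log(2); s <- 0.05
  fit <- make_fake_fit(b0 = mu)
  info <- list(H = diag(c(s^2, 0)))
  sm <- mvn_sampling_se(fit, info, n_samples = 2e4, seed = 12)
  est <- sm$components[sm$components$component == "group[1,1]", ]
  mc_se <- exp(mu) * s / sqrt(2e4)
  expect_lt(abs(est$estimate - exp(mu + s^2 / 2)), 4 * mc_se)
  # SD of draws vs delta-method SE (chi-distribution MC slack)
  expect_lt(abs(est$se - exp(mu) * s), 4 * exp(mu) * s / sqrt(2 * 2e4))
  expect_equal(sm$n_rejected, 0)
})

test_that("degenerate sampling covariance gives zero standard errors", {
  fit <- make_fake_fit()
  sm <- suppressWarnings(mvn_sampling_se(fit, list(H = matrix(0, 2, 2)),
                                         n_samples = 50, seed = 1))
  expect_true(all(sm$components$se == 0))
  expect_equal(sm$components$estimate[sm$components$component == "group[1,1]"],
               2)
  sm2 <- mvn_sampling_se(fit, list(H = diag(c(0.01, 0.01))), n_samples = 200,
                         seed = 5)
  sm3 <- mvn_sampling_se(fit, list(H = diag(c(0.01, 0.01))), n_samples = 200,
                         seed = 5)
  expect_identical(sm2$components, sm3$components)
})

test_that("estimate correlations flag collinear components", {
  fit <- make_fake_fit()
  sm <- mvn_sampling_se(fit, list(H = diag(c(0.02, 0.02))), n_samples = 5000,
                        seed = 31)
  ec <- estimate_correlations(sm)
  cc <- ec$component_correlations
  expect_equal(diag(cc), rep(1, 2), ignore_attr = TRUE)
  # independent parameters: near-zero cross-effect correlation
  expect_lt(abs(cc["group[1,1]", "permanent[1,1]"]), 0.05)
  expect_equal(nrow(ec$flagged), 0)
  # a perfectly collinear pair (same parameter twice) is flagged at |rho|=1
  sm$draws_components <- cbind(sm$draws_components,
                               dup = sm$draws_components[, 1])
  ec2 <- estimate_correlations(sm)
  expect_equal(ec2$component_correlations["group[1,1]", "dup"], 1)
  expect_gte(nrow(ec2$flagged), 1)
})
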