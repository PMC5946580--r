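test_that("polynomial parameter functions evaluate correctly", {
  g <- time_grid(1:5)
  expect_equal(eval_poly(poly_fn(0.5), g), rep(0.5, 5))
  expect_equal(eval_poly(poly_fn(c(0.1, 0.2)), time_grid(3)), 0.7)
  expect_length(eval_poly(poly_fn(c(1, -1, 2)), g), 5)
  # affine time transform shifts the evaluation points
  gt <- time_grid(1:5, transform = c(-3, 1))
  expect_equal(eval_poly(poly_fn(c(0, 1)), gt), (1:5) - 3)
  expect_error(poly_fn(numeric(0)))
  expect_error(time_grid(c(2, 1)))
})

test_that("innovation variances are exp of the log-variance polynomial", {
  g <- time_grid(1:3)
  expect_equal(innovation_variances(sad_spec(list(), poly_fn(0)), g),
               rep(1, 3))
  sp <- sad_spec(list(), poly_fn(c(0, log(2))))
  expect_equal(innovation_variances(sp, time_grid(2)), 4)
  withr::with_seed(1, {
    for (i in 1:10) {
      sp <- sad_spec(list(), poly_fn(runif(3, -2, 2)))
      expect_true(all(innovation_variances(sp, g) > 0))
    }
  })
  expect_error(innovation_variances(sad_spec(list(), poly_fn(1000)), g),
               "overflow")
})

test_that("L and D matrices implement the antedependence recursion", {
  g <- time_grid(1:3)
  ld0 <- build_L_D(sad_spec(list(), poly_fn(0)), g)
  expect_equal(ld0$L, diag(3))
  ld1 <- build_L_D(sad_spec(list(poly_fn(0.5)), poly_fn(0)), g)
  expect_equal(ld1$L[cbind(2:3, 1:2)], c(-0.5, -0.5))
  expect_equal(diag(ld1$L), rep(1, 3))
  # lag-2 term truncated where no such week exists
  g5 <- time_grid(1:5)
  ld2 <- build_L_D(sad_spec(list(poly_fn(0.3), poly_fn(0.2)), poly_fn(0)), g5)
  expect_equal(ld2$L[2, ], c(-0.3, 1, 0, 0, 0))
  expect_equal(ld2$L[3, 1:3], c(-0.2, -0.3, 1))
})

test_that("sigma_from_LD reproduces the forward-recursion covariance", {
  expect_equal(sigma_from_LD(diag(3), diag(3)), diag(3))
  # SAD1 theta=0.5, unit innovations, J=3: frozen forward-recursion values
  ld <- build_L_D(sad_spec(list(poly_fn(0.5)), poly_fn(0)), time_grid(1:3))
  expect_equal(sigma_from_LD(ld$L, ld$D),
               matrix(c(1, .5, .25, .5, 1.25, .625, .25, .625, 1.3125), 3),
               tolerance = 1e-12)
})

test_that("refactoring Sigma recovers theta and D to machine precision", {
  withr::with_seed(7, {
    g <- time_grid(1:5)
    for (i in 1:10) {
      sp <- rand_sad_spec()
      S <- sad_sigma(sp, g)
      dec <- sad_decompose(S)
      ld <- build_L_D(sp, g)
      # theta[j, s] must match -L[j, j-s]; innovations match D
      for (j in 2:5) {
        for (s in seq_len(j - 1)) {
          expect_equal(dec$theta[j, s], -ld$L[j, j - s], tolerance = 1e-9)
        }
      }
      expect_equal(dec$d, diag(ld$D), tolerance = 1e-9)
      expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  })
})

test_that("stationary SAD correlations converge along the diagonal", {
  sp <- sad_spec(list(poly_fn(0.6)), poly_fn(0))
  S <- sad_sigma(sp, time_grid(1:30))
  lag1 <- S[cbind(2:30, 1:29)] / sqrt(diag(S)[2:30] * diag(S)[1:29])
  expect_lt(abs(lag1[29] - 0.6), 1e-6)
  expect_lt(abs(diff(tail(lag1, 2))), 1e-8)
})

test_that("cross-SAD couples DGE to same-week IGE", {
  # J=1: DGE = delta*IGE + e, so var(DGE) = v_D + d^2 v_I, cov = d v_I
  d <- 0.7; vD <- 2; vI <- 3
  cs <- cross_sad_spec(sad_spec(list(), poly_fn(log(vD))),
                       sad_spec(list(), poly_fn(log(vI))),
                       poly_fn(d))
  S <- build_cross_sigma(cs, time_grid(1))
  expect_equal(S[1, 1], vD + d^2 * vI)
  expect_equal(S[1, 2], d * vI)
  expect_equal(S[2, 2], vI)
})

test_that("cross-SAD with zero delta is exactly block-diagonal", {
  withr::with_seed(11, {
    g <- time_grid(1:5)
    for (i in 1:5) {
      p <- rand_sad_spec(2, 1)
      s <- rand_sad_spec(2, 1)
      cs <- cross_sad_spec(p, s, poly_fn(c(0, 0)))
      S <- build_cross_sigma(cs, g)
      expect_equal(S[1:5, 6:10], matrix(0, 5, 5), ignore_attr = TRUE)
      expect_equal(unname(S[1:5, 1:5]), unname(sad_sigma(p, g)))
      expect_equal(unname(S[6:10, 6:10]), unname(sad_sigma(s, g)))
    }
  })
})

test_that("sampled trajectories are reproducible and degenerate correctly", {
  g <- time_grid(1:4)
  sp <- sad_spec(list(poly_fn(0.5)), poly_fn(-60))  # variance ~ 1e-26
  expect_lt(max(abs(sample_effect(sp, g, 1, seed = 3))), 1e-10)
  sp2 <- rand_sad_spec(1, 1)
  expect_identical(sample_effect(sp2, g, 5, seed = 9),
                   sample_effect(sp2, g, 5, seed = 9))
  cs <- cross_sad_spec(sp2, rand_sad_spec(1, 1), poly_fn(-0.3))
  x <- sample_effect(cs, g, 10, seed = 2)
  expect_equal(dim(x), c(10, 8))
})

test_that("SAD structure names follow the order-degree convention", {
  sp <- sad_spec(list(poly_fn(c(0, 0))), poly_fn(c(0, 0)))
  expect_equal(sad_name(sp), "SAD1-11")
  sp2 <- sad_spec(list(poly_fn(0), poly_fn(c(0, 0, 0))), poly_fn(c(0, 0)))
  expect_equal(sad_name(sp2), "SAD2-021")
})
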