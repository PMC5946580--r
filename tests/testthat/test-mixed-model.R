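test_that("design construction follows the social incidence rules", {
  d <- make_social_data(n_cages = 2, J = 2, drop_record = FALSE)
  model <- rand_model(J = 2)
  des <- build_design(d$records, model, d$ped)
  W <- des$W
  J <- 2; K <- des$K
  # each record's IGE incidence has one 1 per cage mate present that week
  gen_cols <- des$offsets[["genetic"]] + seq_len(des$nA * K)
  ige_slots <- as.vector(outer(J + seq_len(J), (seq_len(des$nA) - 1) * K, "+"))
  ige_counts <- Matrix::rowSums(W[, gen_cols[ige_slots], drop = FALSE])
  expect_true(all(ige_counts == 7))
  # no IGE columns without the indirect effect
  des0 <- build_design(d$records, rand_model(J = 2, ige = FALSE), d$ped)
  expect_equal(des0$K, J)

  # unbalanced data: dropping a week removes one row only
  d2 <- make_social_data(n_cages = 2, J = 2, drop_record = TRUE)
  des2 <- build_design(d2$records, model, d2$ped)
  expect_equal(des2$n, des$n - 1)

  expect_error(build_design(rbind(d$records, d$records[1, ]), model, d$ped),
               "duplicate")
  bad <- d$records; bad$animal[1] <- "ghost"
  expect_error(build_design(bad, model, d$ped), "missing from pedigree")
  bad2 <- d$records; bad2$week[1] <- 9
  expect_error(build_design(bad2, model, d$ped), "not on the model grid")
})

test_that("sparse MME likelihood equals the dense-matrix oracle", {
  withr::with_seed(21, {
    for (i in 1:6) {
      d <- make_social_data(n_cages = sample(2:3, 1), cage_size = 4,
                            J = sample(2:3, 1),
                            litters = i %% 2 == 0,
                            drop_record = i %% 3 == 0, seed = 100 + i)
      model <- rand_model(J = length(unique(d$records$week)),
                          litter = "litter" %in% names(d$records),
                          ige = i %% 2 == 1)
      des <- build_design(d$records, model, d$ped)
      om <- pack_params(model)
      expect_equal(reml_loglik(om, des), dense_reml_oracle(des, om)$ll,
                   tolerance = 1e-6)
      # second point exercises the cached-factor update path
      om2 <- om + rnorm(length(om), sd = 0.05)
      expect_equal(reml_loglik(om2, des), dense_reml_oracle(des, om2)$ll,
                   tolerance = 1e-6)
    }
  })
})

test_that("restricted likelihood is invariant to record order and location", {
  d <- make_social_data(n_cages = 2, J = 2, seed = 31)
  model <- rand_model(J = 2)
  om <- pack_params(model)
  des <- build_design(d$records, model, d$ped)
  ll <- reml_loglik(om, des)
  shuf <- d$records[sample(nrow(d$records)), ]
  expect_equal(reml_loglik(om, build_design(shuf, model, d$ped)), ll,
               tolerance = 1e-9)
  shifted <- d$records
  shifted$adg <- shifted$adg + 100
  expect_equal(reml_loglik(om, build_design(shifted, model, d$ped)), ll,
               tolerance = 1e-6)
})

test_that("REML matches the closed-form one-way analysis", {
  withr::with_seed(10, {
    G <- 12; k <- 8
    records <- data.frame(animal = as.character(seq_len(G * k)),
                          group = rep(seq_len(G), each = k), week = 1,
                          adg = rnorm(G * k, 30, 2) +
                            rep(rnorm(G, 0, 1.5), each = k))
    m <- sad_model(genetic = NULL, group = sad_spec(list(), poly_fn(0)),
                   permanent = sad_spec(list(), poly_fn(0)),
                   fixed = ~ 1, grid = time_grid(1))
    fit <- fit_reml(records, model = m, init = "direct", factr = 1e6)
    aov_tab <- summary(stats::aov(adg ~ factor(group), records))[[1]]
    msw <- aov_tab["Residuals", "Mean Sq"]
    msb <- aov_tab[1, "Mean Sq"]
    expect_equal(exp(fit$omega[[2]]), msw, tolerance = 1e-5)
    expect_equal(exp(fit$omega[[1]]), (msb - msw) / k, tolerance = 1e-4)
  })
})

test_that("refitting from the solution is a fixed point", {
  d <- make_social_data(n_cages = 2, cage_size = 4, J = 2, seed = 33,
                        litters = FALSE)
  model <- rand_model(J = 2, litter = FALSE, ige = FALSE)
  fit <- fit_reml(d$records, model = model, ped = d$ped, init = "direct")
  refit <- fit_reml(d$records, model = model, ped = d$ped, init = fit$omega)
  expect_lt(abs(refit$loglik - fit$loglik), 1e-4)
})

test_that("likelihood-ratio test uses literal parameter-count df", {
  fit <- list(loglik = -100, n_params = 18)
  expect_equal(lrt(fit, fit), list(statistic = 0, df = 0, p_value = NA_real_))
  red <- list(loglik = -105, n_params = 12)
  l <- lrt(fit, red)
  expect_equal(l$statistic, 10)
  expect_equal(l$df, 6)
  expect_equal(l$p_value, pchisq(10, 6, lower.tail = FALSE))
  expect_error(lrt(red, list(loglik = -90, n_params = 10)), "negative")
})

test_that("identifiability diagnostics report condition numbers", {
  info <- list(info = diag(2), H = diag(2))
  expect_equal(identifiability_diagnostics(info)$condition, 1)
  info2 <- list(info = diag(c(4, 1)), H = diag(c(0.25, 1)))
  dg <- identifiability_diagnostics(info2, subset = 1)
  expect_equal(dg$condition, 2)
  expect_equal(dg$condition_subset, 1)
  expect_true(dg$psd)
  expect_equal(dim(dg$param_correlations), c(2, 2))
})

test_that("BLUP solves the mixed-model equations", {
  d <- make_social_data(n_cages = 3, J = 1, seed = 24, litters = FALSE,
                        drop_record = FALSE)
  model <- rand_model(J = 1, litter = FALSE)
  om <- pack_params(model)
  des <- build_design(d$records, model, d$ped)
  bl <- predict_blup(des, om)
  orc <- dense_reml_oracle(des, om)
  expect_equal(unname(bl$fixed), unname(orc$beta), tolerance = 1e-6)
  u_g <- bl$solution[des$offsets[["genetic"]] + seq_len(des$nA * des$K)]
  expect_equal(u_g, orc$u_g, tolerance = 1e-6)
  # recordless ancestors still receive EBVs
  expect_true(all(d$ped$animal %in% bl$ebv$animal))

  # zero phenotypic deviations give zero EBVs
  d0 <- d$records
  d0$adg <- 5
  bl0 <- predict_blup(build_design(d0, model, d$ped), om)
  expect_lt(max(abs(bl0$ebv$dge)), 1e-8)
  expect_lt(max(abs(bl0$ebv$ige)), 1e-8)
})

test_that("EBVs correlate positively with true breeding values", {
  withr::with_seed(40, {
    params <- sim_parameters("weak")
    config <- sim_config(n_sires = 10, n_dams = 40, dams_per_sire = 4,
                         offspring_per_mating = 8)
    base <- simulate_base(params, config, seed = 40)
    ped <- pedigree(base$animals$id, base$animals$sire, base$animals$dam)
    model <- default_sad_model(TRUE)
    # BLUP at rough (data-driven, not estimated) variance components is
    # enough for a positive EBV-truth correlation
    des <- build_design(base$records, model, ped)
    bl <- predict_blup(des, sadige:::default_start(des))
    ebv <- bl$ebv[bl$ebv$animal %in% base$cohort$id, ]
    ebv <- ebv[order(ebv$animal, ebv$week), ]
    tru <- base$bv[sort(base$cohort$id), ]
    dge_sum <- tapply(ebv$dge, ebv$animal, sum)
    expect_gt(cor(dge_sum, rowSums(tru[names(dge_sum), 1:5])), 0.2)
  })
})
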