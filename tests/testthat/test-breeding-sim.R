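test_that("founder simulation matches the base-population design", {
  params <- sim_parameters("strong")
  fnd <- simulate_founders(params, sim_config(), seed = 2)
  expect_equal(sum(fnd$animals$sex == "M"), 30)
  expect_equal(sum(fnd$animals$sex == "F"), 120)
  expect_equal(nrow(fnd$bv), 150)
  # zero genetic covariance -> all breeding values zero
  p0 <- params
  p0$genetic <- matrix(0, 10, 10)
  expect_equal(max(abs(simulate_founders(p0, sim_config(), seed = 2)$bv)), 0)
})

test_that("offspring breeding values follow the Mendelian sampling rule", {
  params <- sim_parameters("strong")
  cfg <- sim_config(n_sires = 1, n_dams = 1, dams_per_sire = 1,
                    offspring_per_mating = 20000, n_generations = 1)
  pbv <- matrix(c(rnorm(10), rnorm(10)), 2, 10, byrow = TRUE,
                dimnames = list(c("S", "D"), NULL))
  off <- mate_and_drop(data.frame(sire = "S", dam = "D"), pbv, params, cfg,
                       seed = 4)
  expect_equal(nrow(off$bv), 20000)
  # within-family mean at the parent average, covariance at half Sigma_GE
  mid <- 0.5 * (pbv[1, ] + pbv[2, ])
  emp_mean <- colMeans(off$bv)
  emp_cov <- cov(off$bv)
  se_mean <- sqrt(diag(params$genetic) / 2 / 20000)
  expect_true(all(abs(emp_mean - mid) < 4 * se_mean))
  half <- params$genetic / 2
  mc_se <- sqrt((outer(diag(half), diag(half)) + half^2) / 20000)
  expect_true(all(abs(emp_cov - half) < 4 * mc_se + 1e-8))

  # zero parents and zero covariance -> zero offspring
  p0 <- params
  p0$genetic <- matrix(0, 10, 10)
  off0 <- mate_and_drop(data.frame(sire = "S", dam = "D"), pbv * 0, p0,
                        sim_config(n_sires = 1, n_dams = 1, dams_per_sire = 1,
                                   offspring_per_mating = 8,
                                   n_generations = 1), seed = 1)
  expect_equal(max(abs(off0$bv)), 0)
})

test_that("standard mating design yields the 960-offspring cohort", {
  params <- sim_parameters("moderate")
  base <- simulate_base(params, sim_config(), seed = 3)
  expect_equal(nrow(base$cohort), 960)
  expect_equal(nrow(base$records), 4800)
  expect_equal(length(unique(base$records$group)), 120)
})

test_that("cage assignment is a 4-family x 2-progeny partition", {
  params <- sim_parameters("strong")
  base <- simulate_base(params, sim_config(), seed = 9)
  groups <- assign_groups(base$cohort, sim_config(), seed = 17)
  expect_equal(nrow(groups), 960)
  expect_false(anyDuplicated(groups$animal) > 0)
  fam <- base$cohort$family[match(groups$animal, base$cohort$id)]
  for (g in split(fam, groups$group)) {
    expect_length(g, 8)
    expect_equal(sort(unname(table(g))), c(2, 2, 2, 2), ignore_attr = TRUE)
  }
  expect_identical(groups, assign_groups(base$cohort, sim_config(), seed = 17))
})

test_that("phenotype generation wires the social incidence correctly", {
  params <- sim_parameters("strong")
  cfg <- sim_config()
  base <- simulate_base(params, cfg, seed = 5)
  # zero everything -> phenotype equals the week mean exactly
  p0 <- params
  p0$genetic <- matrix(0, 10, 10)
  p0$group <- matrix(0, 5, 5)
  p0$permanent <- matrix(0, 5, 5)
  fnd <- simulate_founders(p0, cfg, seed = 1)
  mat <- data.frame(sire = fnd$animals$id[1:30][rep(1:30, each = 4)],
                    dam = fnd$animals$id[30 + 1:120])
  off <- mate_and_drop(mat, fnd$bv, p0, cfg, seed = 1)
  grp <- assign_groups(off$animals, cfg, seed = 1)
  rec <- generate_phenotypes(off$animals, off$bv, grp, p0, seed = 1)
  mns <- p0$means[rec$week]
  expect_equal(rec$adg, unname(mns))

  # perturbing one animal's IGE changes exactly its 7 cage mates' records
  bv2 <- base$bv
  victim <- base$cohort$id[1]
  bv2[victim, 6:10] <- bv2[victim, 6:10] + 1
  rec1 <- generate_phenotypes(base$cohort, base$bv, base$groups, params,
                              seed = 77)
  rec2 <- generate_phenotypes(base$cohort, bv2, base$groups, params,
                              seed = 77)
  changed <- unique(rec1$animal[rec1$adg != rec2$adg])
  mates <- setdiff(base$groups$animal[base$groups$group ==
                     base$groups$group[base$groups$animal == victim]], victim)
  expect_setequal(changed, mates)
})

test_that("generation-0 phenotypic means and variances match the truth", {
  params <- sim_parameters("strong")
  withr::with_seed(50, {
    base <- simulate_base(params, sim_config(), seed = 50)
    wk_mean <- tapply(base$records$adg, base$records$week, mean)
    wk_var <- tapply(base$records$adg, base$records$week, var)
    ped <- pedigree(base$animals$id, base$animals$sire, base$animals$dam)
    A <- build_A(ped)
    r <- mean_cage_relatedness(A, base$groups)
    cp <- variance_components(list(genetic = params$genetic,
                                   group = params$group,
                                   permanent = params$permanent))
    expect_v <- total_phenotypic_variance(cp, 8, r)
    # means: SE ~ sqrt(var/960) times a correlation-inflation allowance
    expect_true(all(abs(wk_mean - params$means) <
                      4 * sqrt(expect_v / 960) * 2))
    expect_true(all(abs(wk_var / expect_v - 1) < 0.25))
  })
})

test_that("total EBV combines direct and indirect effects by group size", {
  expect_equal(compute_tebv(1, 0.5), 4.5)
  expect_equal(compute_tebv(2, 0), 2)
  expect_equal(compute_tebv(1, 0.5, group_size = 2), 1.5)
  expect_equal(compute_tebv(c(1, 2), c(0, 1)), c(1, 9))
})

test_that("breeder selection respects family constraints and tie-breaks", {
  params <- sim_parameters("strong")
  base <- simulate_base(params, sim_config(), seed = 12)
  cohort <- base$cohort
  crit <- setNames(rnorm(nrow(cohort)), cohort$id)
  sel <- select_breeders(cohort, crit, sim_config(), seed = 3)
  expect_length(sel$males, 30)
  expect_length(sel$females, 120)
  # each selected male is the criterion maximum of his sire family
  sires_of <- cohort$sire[match(sel$males, cohort$id)]
  expect_false(anyDuplicated(sires_of) > 0)
  for (m in sel$males) {
    fam_males <- cohort$id[cohort$sire == cohort$sire[cohort$id == m] &
                             cohort$sex == "M"]
    expect_equal(crit[[m]], max(crit[fam_males]))
  }
  # no mating pairs animals of the same sire family
  ms <- cohort$sire[match(sel$matings$sire, cohort$id)]
  ds <- cohort$sire[match(sel$matings$dam, cohort$id)]
  expect_true(all(ms != ds))
  expect_equal(unname(table(sel$matings$sire)), rep(4L, 30),
               ignore_attr = TRUE)

  # equal criterion values: stable tie-break by lowest id
  tie <- setNames(rep(1, nrow(cohort)), cohort$id)
  sel_tie <- select_breeders(cohort, tie, sim_config(), seed = 3)
  by_family <- split(cohort$id[cohort$sex == "M"],
                     cohort$sire[cohort$sex == "M"])
  expect_setequal(sel_tie$males, vapply(by_family, min, ""))
  fem <- sort(cohort$id[cohort$sex == "F"])[1:120]
  expect_setequal(sel_tie$females, fem)
})

test_that("recovery study is exact under an oracle fitter", {
  params <- sim_parameters("strong")
  oracle <- function(records, model, ped) {
    list(sigma = list(genetic = params$genetic, group = params$group),
         convergence = TRUE)
  }
  rs <- recovery_study(params, sim_config(), replicates = 2, seed = 1,
                       fitter = oracle)
  expect_equal(rs$pct_converged, 100)
  expect_true(all(abs(rs$table$average) < 1e-10))
  expect_true(all(abs(rs$table$min) < 1e-10))
  expect_true(all(abs(rs$table$max) < 1e-10))
})

test_that("recovery bias and dispersion match hand-computed values", {
  params <- sim_parameters("strong")
  # three preset "estimates": truth scaled by 0.8, 1.0 and 1.5
  scales <- c(0.8, 1.0, 1.5)
  counter <- new.env(); counter$i <- 0
  fitter <- function(records, model, ped) {
    counter$i <- counter$i + 1
    s <- scales[counter$i]
    list(sigma = list(genetic = params$genetic * s, group = params$group * s),
         convergence = TRUE)
  }
  rs <- recovery_study(params, sim_config(), replicates = 3, seed = 1,
                       fitter = fitter)
  tab <- rs$table
  # variances: mean estimate = 1.1 * truth -> relative bias 10%; CV is
  # sd(scales)/mean(scales) since every variance scales identically
  for (comp in c("direct_var", "indirect_var", "group_var")) {
    row <- tab[tab$component == comp & tab$criterion == "relative_bias_pct", ]
    expect_equal(row$average, 10, tolerance = 1e-9)
    row_cv <- tab[tab$component == comp & tab$criterion == "cv_pct", ]
    expect_equal(row_cv$average, 100 * sd(scales) / mean(scales),
                 tolerance = 1e-9)
  }
  # correlations are scale-invariant -> zero bias, zero SD
  for (comp in c("direct_cor", "indirect_cor", "direct_indirect_cor",
                 "group_cor")) {
    sub <- tab[tab$component == comp, ]
    expect_true(all(abs(sub$average) < 1e-10))
  }
})

test_that("random selection yields no systematic response", {
  params <- sim_parameters("moderate")
  withr::with_seed(61, {
    resp <- vapply(1:2, function(r) {
      base <- simulate_base(params, sim_config(), seed = 600 + r)
      run <- run_scenario(base, 3, seed = 700 + r, random_selection = TRUE)
      n <- nrow(run$response)
      run$response$mean_adg[n] - run$response$mean_adg[1]
    }, 0)
    # genetic SD of the cohort mean TBV is ~0.3 g/d; random drift over 7
    # generations stays within ~1.5 g/d
    expect_lt(abs(mean(resp)), 1.5)
  })
})
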