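#' Simulate the base population of the selection study
#'
#' Founders, their 960-offspring base cohort, cage assignment and weekly
#' phenotypes — the records on which variance components are estimated.
#'
#' @param params A [sim_parameters()] bundle.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List of class `sim_base` with the cumulative `animals` table,
#'   `bv` matrix, `records`, `groups` and the base-cohort ids.
#' @export
simulate_base <- function(params, config = sim_config(), seed = NULL) {
  with_seed(seed, {
    fnd <- simulate_founders(params, config)
    matings <- data.frame(
      sire = rep(fnd$animals$id[seq_len(config$n_sires)],
                 each = config$dams_per_sire),
      dam = fnd$animals$id[config$n_sires + seq_len(config$n_dams)],
      stringsAsFactors = FALSE)
    off <- mate_and_drop(matings, fnd$bv, params, config, generation = 1L)
    groups <- assign_groups(off$animals, config, prefix = "g1c")
    records <- generate_phenotypes(off$animals, off$bv, groups, params)
    fnd$animals$family <- NA_integer_
    structure(list(animals = rbind(fnd$animals, off$animals),
                   bv = rbind(fnd$bv, off$bv),
                   cohort = off$animals, records = records, groups = groups,
                   params = params, config = config),
              class = "sim_base")
  })
}

scenario_model <- function(scenario) {
  default_sad_model(include_ige = scenario %in% c(2L, 3L), litter = FALSE)
}

# Starting values for replicated-study fits: the SAD approximation of the
# generating parameters (the usual practice of starting REML at plausible
# literature values). The with-IGE likelihood surface is multi-modal, with
# an inferior mode at near-zero indirect variance; a well-placed start
# avoids it far more cheaply than multi-start searches.
params_start <- function(model, params) {
  J <- length(params$means)
  sig <- list(group = params$group, permanent = params$permanent)
  if (isTRUE(model$include_ige)) {
    sig$genetic <- params$genetic
  } else if (!is.null(model$genetic)) {
    sig$genetic <- params$genetic[seq_len(J), seq_len(J)]
  }
  approx_sad_params(model, sig)
}

study_fit <- function(records, model, ped, params, fit_args) {
  if (is.null(fit_args$init)) {
    fit_args$init <- params_start(model, params)
  }
  do.call(fit_reml, c(list(records, model = model, ped = ped), fit_args))
}

selection_criterion <- function(blup, cohort_ids, scenario, group_size) {
  ebv <- blup$ebv[blup$ebv$animal %in% cohort_ids, , drop = FALSE]
  val <- if (scenario == 1L) {
    tapply(ebv$dge, ebv$animal, sum)
  } else {
    tebv <- compute_tebv(ebv$dge, ebv$ige, group_size)
    if (scenario == 2L) {
      tapply(ifelse(ebv$week == min(ebv$week), tebv, 0), ebv$animal, sum)
    } else {
      tapply(tebv, ebv$animal, sum)
    }
  }
  stats::setNames(as.numeric(val), names(val))
}

#' Run one selection scenario over the full breeding program
#'
#' Variance components are estimated once by REML on the base cohort's
#' records under the scenario's evaluation model (scenario 1: SAD model
#' without IGE, selection on the summed weekly direct EBV; scenario 2:
#' SAD model with IGE, selection on the week-1 total EBV; scenario 3: with
#' IGE, selection on the summed weekly total EBV), then fixed and treated
#' as known. Each generation, EBVs are predicted by BLUP from all records
#' accumulated so far, breeders are selected ([select_breeders()]), and the
#' next cohort is bred, caged and phenotyped.
#'
#' @param base A [simulate_base()] population (share it across scenarios of
#'   one replicate to use common random numbers for the base cohort).
#' @param scenario 1, 2 or 3.
#' @param seed Integer seed for the post-base generations.
#' @param fit Optional pre-computed [fit_reml()] result for the scenario's
#'   model on the base records (scenarios 2 and 3 can share one fit).
#' @param random_selection Replace the criterion by random choice (control).
#' @param fit_args Extra arguments passed to [fit_reml()] for the base fit
#'   (e.g. `factr` to trade optimizer endgame precision for speed).
#' @return List of class `scenario_result`: `response` (data frame with
#'   per-generation overall and per-week mean ADG), `fit`, `converged`.
#' @export
run_scenario <- function(base, scenario, seed = NULL, fit = NULL,
                         random_selection = FALSE, fit_args = list()) {
  scenario <- as.integer(scenario)
  stopifnot(scenario %in% 1:3)
  config <- base$config
  params <- base$params
  model <- scenario_model(scenario)

  make_ped <- function(animals) pedigree(animals$id, animals$sire, animals$dam)

  if (is.null(fit) && !random_selection) {
    fit <- study_fit(base$records, model, make_ped(base$animals),
                     base$params, fit_args)
  }

  with_seed(seed, {
    animals <- base$animals
    bv <- base$bv
    cohort <- base$cohort
    records <- base$records
    J <- length(params$means)

    gen_summary <- function(cohort_ids, recs, generation) {
      sub <- recs[recs$animal %in% cohort_ids, , drop = FALSE]
      wk <- tapply(sub$adg, sub$week, mean)
      out <- data.frame(generation = generation, mean_adg = mean(sub$adg))
      out[paste0("week", seq_len(J))] <- as.numeric(wk[as.character(seq_len(J))])
      out
    }
    response <- gen_summary(cohort$id, records, 0L)

    for (gen in seq_len(config$n_generations)) {
      if (random_selection) {
        crit <- stats::setNames(numeric(nrow(cohort)), cohort$id)
      } else {
        blup <- predict_blup(records, fit$omega, model = fit$model,
                             ped = make_ped(animals))
        crit <- selection_criterion(blup, cohort$id, scenario, config$group_size)
      }
      sel <- select_breeders(cohort, crit, config, random = random_selection)
      off <- mate_and_drop(sel$matings, bv, params, config, generation = gen + 1L)
      groups <- assign_groups(off$animals, config, prefix = sprintf("g%dc", gen + 1L))
      new_rec <- generate_phenotypes(off$animals, off$bv, groups, params)

      animals <- rbind(animals, off$animals)
      bv <- rbind(bv, off$bv)
      cohort <- off$animals
      records <- rbind(records, new_rec)
      response <- rbind(response, gen_summary(cohort$id, new_rec, gen))
    }
    structure(list(response = response, fit = fit, scenario = scenario,
                   converged = is.null(fit) || fit$convergence),
              class = "scenario_result")
  })
}

#' Replicated comparison of the three selection strategies
#'
#' Runs `replicates` independent base populations; within a replicate the
#' three scenarios share the base cohort (common random numbers) and
#' scenarios 2 and 3 share the with-IGE base fit. Replicates whose base
#' fit(s) did not converge are flagged and excluded from the summary,
#' mirroring the study's treatment of non-converged replicates.
#'
#' @param params A [sim_parameters()] bundle.
#' @param config A [sim_config()].
#' @param scenarios Integer subset of 1:3.
#' @param replicates Number of replicates.
#' @param seed Integer base seed; replicate r uses `seed + r`.
#' @param fit_args Extra arguments passed to [fit_reml()] for the base fits.
#' @return List of class `selection_study`: per-replicate scenario results
#'   and a `summary` data frame of generation-7 responses.
#' @export
selection_study <- function(params, config = sim_config(), scenarios = 1:3,
                            replicates = 3, seed = 1, fit_args = list()) {
  reps <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    rseed <- seed + r
    base <- simulate_base(params, config, seed = rseed)
    ped <- pedigree(base$animals$id, base$animals$sire, base$animals$dam)
    fits <- list()
    if (any(scenarios != 1L)) {
      fits$ige <- study_fit(base$records, scenario_model(3L), ped, params,
                            fit_args)
    }
    if (1L %in% scenarios) {
      fits$noige <- study_fit(base$records, scenario_model(1L), ped, params,
                              fit_args)
    }
    converged <- all(vapply(fits, function(f) f$convergence, TRUE))
    runs <- list()
    for (sc in scenarios) {
      f <- if (sc == 1L) fits$noige else fits$ige
      runs[[as.character(sc)]] <- run_scenario(base, sc, seed = rseed * 13L + sc,
                                               fit = f)
    }
    reps[[r]] <- list(runs = runs, converged = converged)
  }
  used <- which(vapply(reps, function(x) x$converged, TRUE))
  summ <- do.call(rbind, lapply(used, function(r) {
    do.call(rbind, lapply(reps[[r]]$runs, function(run) {
      resp <- run$response
      last <- resp[nrow(resp), ]
      base0 <- resp[1, ]
      data.frame(replicate = r, scenario = run$scenario,
                 response = last$mean_adg - base0$mean_adg,
                 t(as.numeric(last[paste0("week", 1:5)]) -
                   as.numeric(base0[paste0("week", 1:5)])))
    }))
  }))
  if (!is.null(summ)) {
    names(summ)[4:8] <- paste0("resp_week", 1:5)
  }
  structure(list(replicates = reps, summary = summ,
                 pct_converged = 100 * length(used) / replicates),
            class = "selection_study")
}

# ---- parameter-recovery study ----------------------------------------------

cor_offdiag <- function(m) m[upper.tri(m)]

#' Parameter-recovery study for the SAD model with IGE
#'
#' Repeatedly simulates the base population, fits the with-IGE SAD model to
#' the base cohort's records, and summarizes bias and dispersion of the
#' reconstructed (co)variance components against the simulation truth:
#' mean relative bias (%) and coefficient of variation for variances, mean
#' bias and standard deviation for correlations, each averaged over weeks
#' (5 values) or week pairs (10 or 25 values) with their range.
#' Non-converged replicates are excluded and their percentage reported.
#'
#' @param params A [sim_parameters()] bundle (the truth).
#' @param config A [sim_config()].
#' @param replicates Number of simulation replicates.
#' @param seed Integer base seed; replicate r uses `seed + r`.
#' @param fitter Function `(records, model, ped) -> sad_fit`-like list with
#'   elements `sigma$genetic`, `sigma$group`, `convergence`. Defaults to
#'   [fit_reml()]; injectable for pipeline checks.
#' @param fit_args Extra arguments passed to [fit_reml()] by the default
#'   fitter.
#' @return List of class `recovery_result` with `table` (component class x
#'   criterion summary), `estimates` (per-replicate arrays) and
#'   `pct_converged`.
#' @export
recovery_study <- function(params, config = sim_config(), replicates = 30,
                           seed = 1, fitter = NULL, fit_args = list()) {
  if (is.null(fitter)) {
    fitter <- function(records, model, ped) {
      study_fit(records, model, ped, params, fit_args)
    }
  }
  model <- scenario_model(3L)
  est <- list()
  n_conv <- 0L
  for (r in seq_len(replicates)) {
    base <- simulate_base(params, config, seed = seed + r)
    ped <- pedigree(base$animals$id, base$animals$sire, base$animals$dam)
    fit <- fitter(base$records, model, ped)
    if (!isTRUE(fit$convergence)) next
    n_conv <- n_conv + 1L
    est[[n_conv]] <- list(genetic = fit$sigma$genetic, group = fit$sigma$group)
  }
  if (n_conv == 0L) stopf("no replicate converged")

  truth <- list(genetic = params$genetic, group = params$group)
  pull <- function(f) vapply(est, f, f(truth))  # components x replicates

  comp <- list(
    direct_var = function(x) diag(x$genetic)[1:5],
    indirect_var = function(x) diag(x$genetic)[6:10],
    group_var = function(x) diag(x$group),
    direct_cor = function(x) cor_offdiag(stats::cov2cor(x$genetic[1:5, 1:5])),
    indirect_cor = function(x) cor_offdiag(stats::cov2cor(x$genetic[6:10, 6:10])),
    direct_indirect_cor = function(x) {
      d <- sqrt(diag(x$genetic))
      as.vector(x$genetic[1:5, 6:10] / outer(d[1:5], d[6:10]))
    },
    group_cor = function(x) cor_offdiag(stats::cov2cor(x$group))
  )
  rows <- lapply(names(comp), function(nm) {
    f <- comp[[nm]]
    tr <- f(truth)
    em <- matrix(pull(f), nrow = length(tr))
    mean_est <- rowMeans(em)
    sd_est <- apply(em, 1, stats::sd)
    if (grepl("_var$", nm)) {
      bias <- (mean_est - tr) / tr * 100
      disp <- sd_est / mean_est * 100
      crit <- c("relative_bias_pct", "cv_pct")
    } else {
      bias <- mean_est - tr
      disp <- sd_est
      crit <- c("bias", "sd")
    }
    data.frame(component = nm,
               criterion = crit,
               average = c(mean(bias), mean(disp)),
               min = c(min(bias), min(disp)),
               max = c(max(bias), max(disp)),
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows), estimates = est,
                 truth = truth,
                 pct_converged = 100 * n_conv / replicates,
                 replicates = replicates),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery_result: %d replicates, %.0f%% converged>\n",
              x$replicates, x$pct_converged))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
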