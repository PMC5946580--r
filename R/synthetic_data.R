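#' Specification of a synthetic longitudinal growth dataset
#'
#' Describes a rabbit-like design: litters of full sibs from a two-
#' generation pedigree (each sire serving several dams), weaned kits mixed
#' into cages of 8, five weekly average-daily-gain records per animal, and
#' cage-level attrition that removes whole cages from a given week onward
#' (diseased or death-affected cages are discarded wholesale). Defaults
#' approximate the analysed experiment: ~1100 litters, ~3000 recorded
#' kits, per-week record counts declining to about 56% of the cohort by
#' week 5.
#'
#' @param n_litters Number of litters.
#' @param litter_sizes Integer vector sampled from (with replacement) for
#'   the number of recorded kits per litter.
#' @param dams_per_sire Dams served by each founder sire.
#' @param cage_size Animals per cage (default 8).
#' @param weeks Measurement week indices.
#' @param genetic,litter,group,permanent Effect covariance matrices
#'   (genetic is 2J x 2J, DGE block first).
#' @param means Weekly mean ADG (g/d).
#' @param attrition Per-week probability that a surviving cage stays in
#'   the dataset that week (applied cumulatively; week 1 value allows
#'   whole-cage week-1 losses).
#' @param per_animal_attrition If `TRUE`, attrition acts on single animals
#'   instead of whole cages.
#' @return List of class `dataset_spec`.
#' @export
dataset_spec <- function(n_litters = 1100,
                         litter_sizes = c(1, 2, 2, 3, 3, 3, 4, 4, 5),
                         dams_per_sire = 4,
                         cage_size = 8,
                         weeks = 1:5,
                         genetic = default_genetic_covariance("strong"),
                         litter = default_litter_covariance(),
                         group = default_group_covariance(),
                         permanent = default_permanent_covariance(),
                         means = default_week_means(),
                         attrition = c(0.87, 0.977, 0.869, 0.852, 0.885),
                         per_animal_attrition = FALSE) {
  J <- length(weeks)
  stopifnot(nrow(genetic) == 2L * J, nrow(litter) == J, nrow(group) == J,
            nrow(permanent) == J, length(means) == J, length(attrition) == J)
  for (m in list(genetic, litter, group, permanent)) {
    if (!is_psd(m)) stopf("covariance matrix is not positive semi-definite")
  }
  structure(list(n_litters = n_litters, litter_sizes = litter_sizes,
                 dams_per_sire = dams_per_sire, cage_size = cage_size,
                 weeks = weeks, genetic = genetic, litter = litter,
                 group = group, permanent = permanent, means = means,
                 attrition = attrition,
                 per_animal_attrition = per_animal_attrition),
            class = "dataset_spec")
}

#' Sample correlated effect trajectories down a pedigree
#'
#' Draws animal-level multivariate effects distributed as
#' \eqn{N(0, A \otimes \Sigma)} by walking the pedigree: founders are
#' i.i.d. \eqn{N(0, \Sigma)}, descendants get the parent average plus a
#' Mendelian sampling deviation with covariance \eqn{d_i \Sigma}, where
#' \eqn{d_i} accounts for known parents and their inbreeding. Cost is
#' linear in the number of animals.
#'
#' @param ped A [pedigree()].
#' @param sigma Within-animal covariance (columns of the result).
#' @param seed Optional integer seed.
#' @return Matrix with one row per animal (pedigree order, rownames =
#'   animal ids).
#' @export
pedigree_aware_mvn_sample <- function(ped, sigma, seed = NULL) {
  with_seed(seed, {
    n <- nrow(ped)
    k <- nrow(sigma)
    dvec <- mendelian_d(ped)
    z <- rmvn(n, sigma)  # unit-scale deviations, scaled per animal below
    out <- matrix(0, n, k, dimnames = list(ped$animal, colnames(sigma)))
    for (i in seq_len(n)) {
      s <- ped$si[i]; d <- ped$di[i]
      par_avg <- 0
      if (s > 0L) par_avg <- par_avg + 0.5 * out[s, ]
      if (d > 0L) par_avg <- par_avg + 0.5 * out[d, ]
      out[i, ] <- par_avg + sqrt(dvec[i]) * z[i, ]
    }
    out
  })
}

#' Generate a synthetic longitudinal dataset
#'
#' Builds the two-generation pedigree, samples every random effect from
#' its multivariate normal (genetic effects through
#' [pedigree_aware_mvn_sample()]), mixes weaned kits into cages, applies
#' attrition and assembles the phenotype table
#' `animal, litter, group, week, adg`.
#'
#' @param spec A [dataset_spec()].
#' @param seed Optional integer seed.
#' @return List of class `synthetic_dataset`: `ped` ([pedigree()]),
#'   `records`, and `truth` (true effect values and the spec).
#' @export
generate_dataset <- function(spec = dataset_spec(), seed = NULL) {
  with_seed(seed, {
    J <- length(spec$weeks)
    n_sires <- ceiling(spec$n_litters / spec$dams_per_sire)
    sires <- sprintf("S%04d", seq_len(n_sires))
    dams <- sprintf("D%04d", seq_len(spec$n_litters))
    lit_sire <- rep(sires, each = spec$dams_per_sire)[seq_len(spec$n_litters)]

    sizes <- sample(spec$litter_sizes, spec$n_litters, replace = TRUE)
    n_kits <- sum(sizes)
    kits <- sprintf("K%05d", seq_len(n_kits))
    kit_lit <- rep(seq_len(spec$n_litters), sizes)

    ped <- pedigree(c(sires, dams, kits),
                    c(rep(NA, n_sires + spec$n_litters), lit_sire[kit_lit]),
                    c(rep(NA, n_sires + spec$n_litters), dams[kit_lit]))

    bv <- pedigree_aware_mvn_sample(ped, spec$genetic)

    # cage assignment: random mixing of weaned kits, surplus kits stay in
    # the pedigree without records
    n_cages <- n_kits %/% spec$cage_size
    caged <- sample(kits, n_cages * spec$cage_size)
    cage <- rep(sprintf("C%04d", seq_len(n_cages)), each = spec$cage_size)
    names(cage) <- caged

    lit_eff <- rmvn(spec$n_litters, spec$litter)
    grp_eff <- rmvn(n_cages, spec$group)
    rownames(grp_eff) <- sprintf("C%04d", seq_len(n_cages))
    perm_eff <- rmvn(length(caged), spec$permanent)
    rownames(perm_eff) <- caged

    # cage-level (default) or animal-level attrition: present from week 1
    # until the first failed continuation draw
    n_units <- if (spec$per_animal_attrition) length(caged) else n_cages
    alive <- matrix(FALSE, n_units, J)
    surv <- rep(TRUE, n_units)
    for (j in seq_len(J)) {
      surv <- surv & (stats::runif(n_units) < spec$attrition[j])
      alive[, j] <- surv
    }

    kit_pos <- match(caged, ped$animal)
    lit_of <- kit_lit[match(caged, kits)]
    dge <- bv[kit_pos, seq_len(J), drop = FALSE]
    ige <- bv[kit_pos, J + seq_len(J), drop = FALSE]
    ige_tot <- rowsum(ige, cage[caged])
    mates_ige <- ige_tot[cage[caged], , drop = FALSE] - ige

    y <- matrix(spec$means, length(caged), J, byrow = TRUE) +
      dge + mates_ige + lit_eff[lit_of, , drop = FALSE] +
      grp_eff[cage[caged], , drop = FALSE] + perm_eff

    unit <- if (spec$per_animal_attrition) seq_along(caged) else
      match(cage[caged], rownames(grp_eff))
    keep <- as.vector(alive[unit, ])  # animals x weeks, column-major
    records <- data.frame(animal = rep(caged, J),
                          litter = rep(dams[lit_of], J),
                          group = rep(cage[caged], J),
                          week = rep(spec$weeks, each = length(caged)),
                          adg = as.vector(y),
                          stringsAsFactors = FALSE)[keep, , drop = FALSE]
    rownames(records) <- NULL

    structure(list(ped = ped, records = records,
                   truth = list(bv = bv, litter_effects = lit_eff,
                                group_effects = grp_eff,
                                permanent_effects = perm_eff,
                                cage = cage, spec = spec)),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d records, %d animals, %d cages>\n",
              nrow(x$records), length(unique(x$records$animal)),
              length(unique(x$records$group))))
  invisible(x)
}
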