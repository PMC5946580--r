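#' Configuration of the closed-nucleus selection simulation
#'
#' Defaults reproduce the study design: 30 unrelated sires each mated to 4
#' unrelated dams (120 dams), 8 offspring per mating with a 50/50 sex
#' ratio (960 offspring per generation, 4800 weekly records), cages of 8
#' drawn from 4 full-sib families contributing 2 progeny each, and 7
#' generations of selection.
#'
#' @param n_sires,n_dams,dams_per_sire,offspring_per_mating,n_generations,group_size,families_per_group,per_family_per_group
#'   Design numbers; see Details defaults.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_sires = 30, n_dams = 120, dams_per_sire = 4,
                       offspring_per_mating = 8, n_generations = 7,
                       group_size = 8, families_per_group = 4,
                       per_family_per_group = 2) {
  stopifnot(n_sires * dams_per_sire == n_dams,
            families_per_group * per_family_per_group == group_size,
            offspring_per_mating %% families_per_group == 0)
  cohort <- n_dams * offspring_per_mating
  stopifnot(cohort %% group_size == 0)
  structure(list(n_sires = n_sires, n_dams = n_dams,
                 dams_per_sire = dams_per_sire,
                 offspring_per_mating = offspring_per_mating,
                 n_generations = n_generations, group_size = group_size,
                 families_per_group = families_per_group,
                 per_family_per_group = per_family_per_group,
                 cohort_size = cohort),
            class = "sim_config")
}

#' Simulate unrelated founders with true breeding-value trajectories
#'
#' Founders are drawn i.i.d. from MVN(0, genetic covariance); the first
#' `n_sires` are male, the remaining `n_dams` female.
#'
#' @param params A [sim_parameters()] bundle (or any list with a `genetic`
#'   matrix).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return List with `animals` (data frame id/sire/dam/sex/generation) and
#'   `bv` (matrix of true breeding values, one row per animal).
#' @export
simulate_founders <- function(params, config = sim_config(), seed = NULL) {
  with_seed(seed, {
    n <- config$n_sires + config$n_dams
    ids <- sprintf("F%03d", seq_len(n))
    animals <- data.frame(id = ids, sire = NA_character_, dam = NA_character_,
                          sex = rep(c("M", "F"), c(config$n_sires, config$n_dams)),
                          generation = 0L, stringsAsFactors = FALSE)
    bv <- rmvn(n, params$genetic)
    rownames(bv) <- ids
    list(animals = animals, bv = bv)
  })
}

#' Mate parents and drop offspring breeding values
#'
#' Offspring true breeding values are the parent average plus a Mendelian
#' sampling deviation drawn from MVN(0, half the genetic covariance).
#' Within each mating, sexes are assigned half male, half female.
#'
#' @param matings Data frame with columns `sire`, `dam` (parent ids).
#' @param parent_bv Matrix of parent breeding values with ids as rownames.
#' @param params A [sim_parameters()] bundle.
#' @param config A [sim_config()].
#' @param generation Integer generation label of the offspring.
#' @param seed Optional integer seed.
#' @return List with `animals` (offspring table, one full-sib `family` per
#'   mating) and `bv`.
#' @export
mate_and_drop <- function(matings, parent_bv, params, config = sim_config(),
                          generation = 1L, seed = NULL) {
  with_seed(seed, {
    k <- config$offspring_per_mating
    nm <- nrow(matings)
    n <- nm * k
    ids <- sprintf("G%d_%04d", generation, seq_len(n))
    fam <- rep(seq_len(nm), each = k)
    animals <- data.frame(id = ids,
                          sire = matings$sire[fam], dam = matings$dam[fam],
                          sex = rep(rep(c("M", "F"), each = k / 2), nm),
                          generation = as.integer(generation),
                          family = fam, stringsAsFactors = FALSE)
    mid <- 0.5 * (parent_bv[matings$sire[fam], , drop = FALSE] +
                  parent_bv[matings$dam[fam], , drop = FALSE])
    bv <- mid + rmvn(n, 0.5 * params$genetic)
    rownames(bv) <- ids
    list(animals = animals, bv = bv)
  })
}

#' Assign a cohort to cages of full-sib family blocks
#'
#' Families are shuffled into blocks of `families_per_group`; each family's
#' offspring are split into pairs and each pair sent to one of the block's
#' groups, so every group holds `per_family_per_group` progeny from each of
#' `families_per_group` distinct full-sib families.
#'
#' @param cohort Offspring table from [mate_and_drop()] (needs `id`,
#'   `family`).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @param prefix Group-id prefix (groups must be unique across generations).
#' @return Data frame with columns `animal`, `group`.
#' @export
assign_groups <- function(cohort, config = sim_config(), seed = NULL,
                          prefix = "grp") {
  with_seed(seed, {
    fams <- unique(cohort$family)
    fpg <- config$families_per_group
    ppf <- config$per_family_per_group
    gpb <- config$offspring_per_mating / ppf  # groups per block
    if (length(fams) %% fpg != 0) stopf("family count not divisible into blocks")
    fams <- sample(fams)
    blocks <- split(fams, rep(seq_len(length(fams) / fpg), each = fpg))
    out <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
      rows <- list()
      for (f in blocks[[b]]) {
        members <- sample(cohort$id[cohort$family == f])
        rows[[length(rows) + 1L]] <-
          data.frame(animal = members,
                     slot = rep(seq_len(gpb), each = ppf),
                     stringsAsFactors = FALSE)
      }
      rows <- do.call(rbind, rows)
      rows$group <- sprintf("%s%03d_%d", prefix, b, rows$slot)
      out[[b]] <- rows[, c("animal", "group")]
    }
    do.call(rbind, out)
  })
}

#' Generate weekly phenotypes for a grouped cohort
#'
#' Each record is the week mean plus the animal's own direct genetic
#' effect, the indirect genetic effects of its cage mates, a week-specific
#' group effect, and a correlated pseudo-permanent effect. No litter effect
#' and no extra residual, matching the selection-simulation model.
#'
#' @param cohort Offspring table (needs `id`).
#' @param bv True breeding-value matrix (rows = ids; columns DGE w1..w5,
#'   IGE w1..w5).
#' @param groups Data frame `animal`/`group` from [assign_groups()].
#' @param params A [sim_parameters()] bundle.
#' @param seed Optional integer seed.
#' @return Phenotype data frame `animal`, `group`, `week`, `adg`.
#' @export
generate_phenotypes <- function(cohort, bv, groups, params, seed = NULL) {
  with_seed(seed, {
    J <- length(params$means)
    ids <- cohort$id
    gmap <- stats::setNames(groups$group, groups$animal)[ids]
    if (anyNA(gmap)) stopf("animal without group assignment")
    dge <- bv[ids, seq_len(J), drop = FALSE]
    ige <- bv[ids, J + seq_len(J), drop = FALSE]
    # sum of mates' IGE = group total - own
    ige_tot <- rowsum(ige, gmap)
    mates_ige <- ige_tot[gmap, , drop = FALSE] - ige

    grp_ids <- rownames(ige_tot)
    g_eff <- rmvn(length(grp_ids), params$group)
    rownames(g_eff) <- grp_ids
    p_eff <- rmvn(length(ids), params$permanent)

    y <- matrix(params$means, length(ids), J, byrow = TRUE) +
      dge + mates_ige + g_eff[gmap, , drop = FALSE] + p_eff
    data.frame(animal = rep(ids, J),
               group = rep(gmap, J),
               week = rep(seq_len(J), each = length(ids)),
               adg = as.vector(y),
               stringsAsFactors = FALSE)
  })
}

#' Select breeders by a criterion and draw next-generation matings
#'
#' Males: within-family truncation, the best male of each sire family
#' (ties broken by lowest id). Females: across-family truncation, the best
#' `n_dams` (same tie-break). Matings: each selected male receives
#' `dams_per_sire` of the selected females at random, never a female from
#' his own sire family.
#'
#' @param cohort Offspring table (needs `id`, `sire`, `sex`).
#' @param criterion Named numeric vector of selection-criterion values
#'   (names = animal ids, covering the cohort).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @param random Select at random instead of by criterion (control runs).
#' @return List with `males`, `females` (ids) and `matings` (data frame
#'   `sire`, `dam`).
#' @export
select_breeders <- function(cohort, criterion, config = sim_config(),
                            seed = NULL, random = FALSE) {
  with_seed(seed, {
    crit <- criterion[cohort$id]
    if (anyNA(crit)) stopf("criterion missing for some cohort animals")
    if (random) crit[] <- stats::runif(length(crit))
    ord <- order(-crit, cohort$id)
    ranked <- cohort[ord, , drop = FALSE]

    males <- ranked[ranked$sex == "M", , drop = FALSE]
    males <- males[!duplicated(males$sire), , drop = FALSE]  # best per sire family
    if (nrow(males) < config$n_sires) stopf("a sire family has no male candidate")
    males <- males[seq_len(config$n_sires), , drop = FALSE]

    females <- ranked[ranked$sex == "F", , drop = FALSE]
    if (nrow(females) < config$n_dams) stopf("fewer than %d female candidates", config$n_dams)
    females <- females[seq_len(config$n_dams), , drop = FALSE]

    # random 1:dams_per_sire matings avoiding shared sire families
    for (attempt in seq_len(200)) {
      pool <- females[sample(nrow(females)), , drop = FALSE]
      assign <- rep(NA_integer_, nrow(pool))
      ok <- TRUE
      quota <- stats::setNames(rep(config$dams_per_sire, nrow(males)), males$id)
      male_sfam <- males$sire[match(names(quota), males$id)]
      for (i in seq_len(nrow(pool))) {
        diff_fam <- is.na(male_sfam) | is.na(pool$sire[i]) |
          male_sfam != pool$sire[i]
        open <- names(quota)[quota > 0 & diff_fam]
        if (!length(open)) { ok <- FALSE; break }
        pick <- if (length(open) == 1L) open else sample(open, 1L)
        assign[i] <- match(pick, males$id)
        quota[pick] <- quota[pick] - 1L
      }
      if (ok && all(quota == 0)) {
        return(list(males = males$id, females = females$id,
                    matings = data.frame(sire = males$id[assign],
                                         dam = pool$id,
                                         stringsAsFactors = FALSE)))
      }
    }
    stopf("could not draw matings satisfying the sire-family constraint")
  })
}
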