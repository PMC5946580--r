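#' Pedigree object
#'
#' Stores animal/sire/dam triples, validates them (unique ids, no animal its
#' own ancestor) and reorders records so that parents always precede their
#' offspring. Unknown parents are coded `0`, `NA` or `""`.
#'
#' @param animal,sire,dam Vectors of ids (coerced to character). `sire` and
#'   `dam` may contain the unknown-parent token.
#' @return An object of class `pedigree`: a data frame with columns
#'   `animal`, `sire`, `dam` in topological order, plus integer index
#'   columns `si`, `di` (0 = unknown).
#' @examples
#' ped <- pedigree(c("s", "d", "a", "b"), c(0, 0, "s", "s"), c(0, 0, "d", "d"))
#' build_A(ped)["a", "b"]  # full sibs: 0.5
#' @export
pedigree <- function(animal, sire, dam) {
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x %in% c("0", "")] <- NA_character_
    x
  }
  animal <- as.character(animal)
  sire <- norm(sire)
  dam <- norm(dam)
  n <- length(animal)
  stopifnot(length(sire) == n, length(dam) == n)
  if (anyDuplicated(animal)) {
    stopf("duplicated animal id: %s", animal[duplicated(animal)][1])
  }
  miss <- setdiff(c(sire, dam), c(animal, NA_character_))
  if (length(miss)) {
    stopf("parent id not in pedigree: %s", miss[1])
  }

  # topological sort (Kahn); failure to place every animal implies a cycle
  idx <- seq_len(n)
  names(idx) <- animal
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  placed <- logical(n)
  ord <- integer(0)
  remaining <- idx
  while (length(remaining)) {
    s_ok <- si[remaining] == 0L | placed[pmax(si[remaining], 1L)]
    d_ok <- di[remaining] == 0L | placed[pmax(di[remaining], 1L)]
    ready <- remaining[s_ok & d_ok]
    if (!length(ready)) stopf("pedigree contains a cycle")
    placed[ready] <- TRUE
    ord <- c(ord, ready)
    remaining <- setdiff(remaining, ready)
  }

  df <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                   stringsAsFactors = FALSE)
  pos <- seq_len(n)
  names(pos) <- df$animal
  df$si <- ifelse(is.na(df$sire), 0L, pos[df$sire])
  df$di <- ifelse(is.na(df$dam), 0L, pos[df$dam])
  class(df) <- c("pedigree", "data.frame")
  df
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree: %d animals, %d founders>\n", nrow(x),
              sum(x$si == 0L & x$di == 0L)))
  invisible(x)
}

# Inbreeding coefficients for every animal. Ancestors of any parent are
# themselves parents, so the parent set is closed under ancestry; a tabular
# A restricted to that (usually small) set gives F_i = 0.5 * A(sire_i, dam_i)
# exactly, in O(P^2 + n).
pedigree_inbreeding <- function(ped) {
  n <- nrow(ped)
  is_par <- logical(n)
  is_par[ped$si[ped$si > 0L]] <- TRUE
  is_par[ped$di[ped$di > 0L]] <- TRUE
  pidx <- which(is_par)
  P <- length(pidx)
  F <- numeric(n)
  if (P == 0L) return(F)
  pos <- integer(n)
  pos[pidx] <- seq_len(P)
  Ap <- matrix(0, P, P)
  for (k in seq_len(P)) {
    i <- pidx[k]
    sp <- if (ped$si[i] > 0L) pos[ped$si[i]] else 0L
    dp <- if (ped$di[i] > 0L) pos[ped$di[i]] else 0L
    if (k > 1L) {
      prev <- seq_len(k - 1L)
      v <- numeric(k - 1L)
      if (sp > 0L) v <- v + 0.5 * Ap[prev, sp]
      if (dp > 0L) v <- v + 0.5 * Ap[prev, dp]
      Ap[prev, k] <- v
      Ap[k, prev] <- v
    }
    Fk <- if (sp > 0L && dp > 0L) 0.5 * Ap[sp, dp] else 0
    Ap[k, k] <- 1 + Fk
    F[i] <- Fk
  }
  for (i in which(!is_par)) {
    if (ped$si[i] > 0L && ped$di[i] > 0L) {
      F[i] <- 0.5 * Ap[pos[ped$si[i]], pos[ped$di[i]]]
    }
  }
  F
}

# Mendelian sampling variances d_i given inbreeding, with the usual
# unknown-parent conventions.
mendelian_d <- function(ped, F = pedigree_inbreeding(ped)) {
  s <- ped$si; d <- ped$di
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], 0)
  both <- s > 0L & d > 0L
  one <- xor(s > 0L, d > 0L)
  out <- rep(1, nrow(ped))
  out[both] <- 0.5 - 0.25 * (Fs[both] + Fd[both])
  out[one] <- 0.75 - 0.25 * (Fs[one] + Fd[one])
  out
}

#' Additive (numerator) relationship matrix
#'
#' Dense tabular-method A with inbreeding accumulation:
#' `A[i,i] = 1 + 0.5 * A[sire, dam]`,
#' `A[i,j] = 0.5 * (A[j, sire] + A[j, dam])` for `j` preceding `i`.
#'
#' @param ped A [pedigree()].
#' @return Dense symmetric matrix with animal ids as dimnames, rows in the
#'   pedigree's topological order.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- ped$si[i]; d <- ped$di[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (s > 0L) v <- v + 0.5 * A[prev, s]
      if (d > 0L) v <- v + 0.5 * A[prev, d]
      A[prev, i] <- v
      A[i, prev] <- v
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with Meuwissen-Luo inbreeding accumulation (set
#' `inbreeding = FALSE` for the classic non-inbred rules). The log
#' determinant of A, `sum(log d_i)` over the Mendelian sampling variances,
#' is attached as attribute `"logdet_A"` (used by the REML likelihood).
#'
#' @param ped A [pedigree()].
#' @param inbreeding Account for inbreeding in the Mendelian sampling
#'   variances (default `TRUE`).
#' @return Sparse symmetric `dsCMatrix` with animal ids as dimnames.
#' @export
build_A_inverse <- function(ped, inbreeding = TRUE) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  dvec <- if (inbreeding) mendelian_d(ped) else {
    mendelian_d(ped, F = numeric(n))
  }
  alpha <- 1 / dvec
  ii <- jj <- xx <- vector("list", n)
  for (i in seq_len(n)) {
    ks <- c(i, ped$si[i], ped$di[i])
    ws <- c(1, -0.5, -0.5)[ks > 0L]
    ks <- ks[ks > 0L]
    # alpha_i * w w' accumulated over the (animal, sire, dam) triple
    m <- length(ks)
    ii[[i]] <- rep(ks, each = m)
    jj[[i]] <- rep(ks, times = m)
    xx[[i]] <- alpha[i] * as.vector(outer(ws, ws))
  }
  Ainv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                               x = unlist(xx), dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Ainv <- Matrix::forceSymmetric(Ainv, uplo = "L")
  attr(Ainv, "logdet_A") <- sum(log(dvec))
  Ainv
}

#' Average genetic relatedness among cage mates
#'
#' Averages the pairwise relationship `A[i, j]` over all unordered pairs of
#' cage mates within each group, then averages over groups.
#'
#' @param A Relationship matrix with animal ids as dimnames (dense or
#'   sparse).
#' @param groups Data frame with columns `animal` and `group`, or a list of
#'   id vectors.
#' @return Scalar mean relatedness.
#' @export
mean_cage_relatedness <- function(A, groups) {
  if (is.data.frame(groups)) {
    groups <- split(as.character(groups$animal), groups$group)
  }
  ids <- rownames(A)
  per_group <- vapply(groups, function(g) {
    g <- as.character(g)
    if (length(g) < 2L) stopf("group with fewer than 2 members")
    if (!all(g %in% ids)) stopf("group member missing from A")
    sub <- as.matrix(A[g, g])
    (sum(sub) - sum(diag(sub))) / (length(g) * (length(g) - 1L))
  }, 0)
  mean(per_group)
}
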