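#' Read a longitudinal phenotype table
#'
#' Delimited text with a header; requires columns `animal`, `group`,
#' `week`, `adg` (a `litter` column and further covariates are kept).
#' Duplicate animal-by-week records and non-numeric ADG values are
#' rejected with the offending key named.
#'
#' @param path File path (comma- or tab-delimited, autodetected).
#' @return Data frame of typed records.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stopf("phenotype file not found: %s", path)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("animal", "group", "week", "adg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  df$animal <- as.character(df$animal)
  df$week <- as.integer(df$week)
  if (anyNA(df$week)) stopf("%s: non-integer week value", path)
  df$adg <- suppressWarnings(as.numeric(df$adg))
  if (anyNA(df$adg)) stopf("%s: non-numeric adg at row %d", path,
                           which(is.na(df$adg))[1])
  key <- paste(df$animal, df$week)
  if (anyDuplicated(key)) {
    stopf("%s: duplicate animal x week record '%s'", path, key[duplicated(key)][1])
  }
  df
}

#' Write a phenotype table
#'
#' @param records Data frame as returned by [read_phenotypes()].
#' @param path Output CSV path.
#' @export
write_phenotypes <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pedigree file
#'
#' Three delimited columns (animal, sire, dam) with a header; `0`, empty
#' or `NA` mark unknown parents. An empty file yields an empty pedigree
#' with a warning.
#'
#' @param path File path.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stopf("pedigree file not found: %s", path)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning(sprintf("%s: empty pedigree", path))
    return(pedigree(character(0), character(0), character(0)))
  }
  if (ncol(df) < 3L) stopf("%s: need animal, sire, dam columns", path)
  pedigree(df[[1]], df[[2]], df[[3]])
}

#' Write a pedigree file
#'
#' @param ped A [pedigree()].
#' @param path Output CSV path.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(animal = ped$animal,
                    sire = ifelse(is.na(ped$sire), 0, ped$sire),
                    dam = ifelse(is.na(ped$dam), 0, ped$dam))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a labelled covariance matrix as CSV
#'
#' Values survive the round trip to at least 12 significant digits.
#'
#' @param m Symmetric matrix with dimnames.
#' @param path CSV path.
#' @export
write_covariance_csv <- function(m, path) {
  df <- as.data.frame(signif(m, 15))
  utils::write.csv(cbind(label = rownames(m), df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_covariance_csv
#' @export
read_covariance_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

# --- SAD model configs -------------------------------------------------------

poly_to_list <- function(fn) list(degree = fn$degree,
                                  coefficients = as.numeric(fn$coefficients))
poly_from_list <- function(x) poly_fn(x$coefficients)

spec_to_list <- function(spec) {
  if (inherits(spec, "cross_sad_spec")) {
    list(type = "cross",
         primary = spec_to_list(spec$primary),
         secondary = spec_to_list(spec$secondary),
         cross = poly_to_list(spec$cross))
  } else {
    list(type = "single", order = spec$order,
         antedependence = lapply(spec$antedependence, poly_to_list),
         innovation_logvar = poly_to_list(spec$innovation_logvar))
  }
}

spec_from_list <- function(x) {
  if (identical(x$type, "cross")) {
    cross_sad_spec(spec_from_list(x$primary), spec_from_list(x$secondary),
                   poly_from_list(x$cross))
  } else {
    sad_spec(lapply(x$antedependence, poly_from_list),
             poly_from_list(x$innovation_logvar))
  }
}

#' Serialize a model specification to / from a YAML config file
#'
#' The config stores, per random effect, the antedependence order, the
#' polynomial coefficients of every lag, the log-innovation-variance
#' coefficients and (for the genetic pair) the cross-antedependence
#' coefficients, plus the week grid and fixed-effect formula. Unknown keys
#' are rejected.
#'
#' @param model A [sad_model()].
#' @param path YAML file path.
#' @export
write_model_config <- function(model, path) {
  cfg <- list(grid = list(weeks = as.numeric(model$grid$weeks),
                          transform = as.numeric(model$grid$transform)),
              fixed = deparse(model$fixed),
              genetic = spec_to_list(model$genetic),
              group = spec_to_list(model$group),
              permanent = spec_to_list(model$permanent))
  if (!is.null(model$litter)) cfg$litter <- spec_to_list(model$litter)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("grid", "fixed", "genetic", "group", "permanent", "litter")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stopf("%s: unknown config key(s): %s", path,
                         paste(bad, collapse = ", "))
  for (k in c("grid", "fixed", "genetic", "group", "permanent")) {
    if (is.null(cfg[[k]])) stopf("%s: missing config key '%s'", path, k)
  }
  sad_model(genetic = spec_from_list(cfg$genetic),
            group = spec_from_list(cfg$group),
            permanent = spec_from_list(cfg$permanent),
            litter = if (!is.null(cfg$litter)) spec_from_list(cfg$litter),
            fixed = stats::as.formula(cfg$fixed),
            grid = time_grid(cfg$grid$weeks, cfg$grid$transform))
}

#' Write a fitted model report to a directory
#'
#' Writes the packed estimates and log-likelihood (YAML), every
#' reconstructed covariance matrix (labelled CSVs) and, if supplied, the
#' EBV table.
#'
#' @param fit A [fit_reml()] result.
#' @param dir Output directory (created if needed).
#' @param blup Optional [predict_blup()] result for the EBV table.
#' @export
write_fit_report <- function(fit, dir, blup = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(loglik = fit$loglik,
                        converged = fit$convergence,
                        n_params = fit$n_params,
                        omega = as.list(stats::setNames(as.numeric(fit$omega),
                                                        names(fit$omega)))),
                   file.path(dir, "fit.yaml"))
  for (nm in names(fit$sigma)) {
    write_covariance_csv(fit$sigma[[nm]],
                         file.path(dir, paste0("sigma_", nm, ".csv")))
  }
  write_model_config(fit$model, file.path(dir, "model.yaml"))
  if (!is.null(blup)) {
    utils::write.csv(blup$ebv, file.path(dir, "ebv.csv"), row.names = FALSE)
  }
  invisible(dir)
}
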