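#' Read and write cohort tables as delimited text
#'
#' Cohorts are exchanged as tab-separated text with one row per patient.
#' `write_cohort` stores all columns including per-component indicators;
#' `read_cohort` restores the `ali_cohort` class (the generator
#' configuration, when needed for synthetic validation, must be supplied
#' separately or rebuilt from a config file).
#'
#' @param cohort an `ali_cohort`.
#' @param path file path.
#' @return `read_cohort` returns an `ali_cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.delim(path, na.strings = "NA")
  need <- c("id", "y", "z", "x_star", "v")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("cohort file lacks column(s): ",
                         paste(miss, collapse = ", "))
  class(out) <- c("ali_cohort", class(out))
  out
}

#' Serialize a sieve MLE fit to JSON and back
#'
#' Stores the coefficients (with SEs/CIs when present), the sieve
#' coefficient matrix, the support grid, and the basis definition, so that
#' prediction can run from the file alone.
#'
#' @param fit an `ali_smle`.
#' @param path file path.
#' @export
write_smle <- function(fit, path) {
  obj <- list(beta = unname(fit$beta), se = fit$se,
              ci = if (!is.null(fit$ci)) unclass(fit$ci),
              p = fit$p, grid = fit$grid,
              basis = list(degree = fit$basis$degree, knots = fit$basis$knots,
                           conditioning = fit$basis$conditioning,
                           z_breaks = fit$basis$z_breaks),
              converged = fit$converged, n_iter = fit$n_iter,
              loglik = utils::tail(fit$loglik_trace, 1),
              n = fit$n, n_validated = fit$n_validated)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_smle
#' @export
read_smle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- structure(list(degree = obj$basis$degree,
                          knots = as.numeric(obj$basis$knots),
                          n_basis = obj$basis$degree + 1L +
                            length(obj$basis$knots),
                          conditioning = obj$basis$conditioning,
                          z_breaks = obj$basis$z_breaks, z_quantiles = NULL),
                     class = "sieve_basis")
  structure(list(beta = stats::setNames(obj$beta,
                                        c("(Intercept)", "ali", "age_decade")),
                 se = obj$se, ci = obj$ci, p = as.matrix(obj$p),
                 grid = obj$grid, basis = basis, converged = obj$converged,
                 n_iter = obj$n_iter, loglik_trace = obj$loglik,
                 n = obj$n, n_validated = obj$n_validated),
            class = "ali_smle")
}

#' Read a run configuration from JSON
#' @param path JSON file.
#' @return named list.
#' @export
read_run_config <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Build an analysis cohort from raw patient measurements
#'
#' Takes one row per patient with the outcome, age, sex, and raw
#' (mean-per-patient) measurements named by component — patients with
#' several encounter values should carry their mean, since components are
#' discretized from mean measurements — and produces an `ali_cohort` with
#' discretized error-prone components and the proportion-style ALI.
#' Measurement columns that are absent are treated as missing for all
#' patients.
#'
#' @param df data frame with columns `y`, `age`, `sex` and any of the
#'   component names in [ali_component_names()]; an optional `id`.
#' @param specs component table from [ali_components()].
#' @return an `ali_cohort` data frame with `z = (age - 18)/10`, component
#'   indicator columns `s_star_*`, `x_star`, and `n_star`; patients with
#'   all ten components missing are an error.
#' @export
cohort_from_measurements <- function(df, specs = ali_components()) {
  stopifnot(all(c("y", "age") %in% names(df)))
  n <- nrow(df)
  nms <- ali_component_names()
  s_star <- matrix(NA_integer_, n, 10L, dimnames = list(NULL, nms))
  for (nm in nms) {
    if (!nm %in% names(df)) next
    s_star[, nm] <- discretize_component(df[[nm]], nm, sex = df$sex,
                                         specs = specs)
  }
  n_star <- rowSums(!is.na(s_star))
  if (any(n_star == 0L))
    stop("ALI is undefined (all ten components missing) for row(s): ",
         paste(utils::head(which(n_star == 0L), 5), collapse = ", "))
  out <- data.frame(
    id = if (is.null(df$id)) seq_len(n) else df$id,
    age = df$age, z = (df$age - 18) / 10, y = df$y,
    x_true = NA_real_,
    x_star = rowSums(s_star == 1L, na.rm = TRUE) / n_star,
    n_star = n_star, v = 0L, x_validated = NA_real_,
    n_validated = NA_integer_)
  colnames(s_star) <- paste0("s_star_", nms)
  out <- cbind(out, as.data.frame(s_star))
  class(out) <- c("ali_cohort", class(out))
  out
}
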