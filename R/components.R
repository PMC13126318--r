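#' Canonical allostatic load index (ALI) component specifications
#'
#' Returns the ten-component specification table used to build the ALI
#' computable phenotype: one binary indicator per physiological measurement,
#' discretized at a clinically driven threshold, grouped into three body
#' systems (cardiovascular, metabolic, inflammation). Each component also
#' carries its audit-roadmap "anchors": diagnosis strings whose presence in a
#' patient's chart lets a chart reviewer recover a missing component as
#' unhealthy. Serum albumin has no anchors and can never be recovered;
#' creatinine clearance has sex-specific thresholds.
#'
#' The shipped table follows the printed clinical reference thresholds,
#' including serum albumin's ">= 3.5 = unhealthy" direction. Because low
#' (not high) albumin is conventionally the unhealthy state, the direction
#' of any component can be overridden via `overrides`.
#'
#' @param overrides optional named list; each element is itself a list of
#'   fields to replace for that component, e.g.
#'   `list(albumin = list(direction = "less", threshold = 3.5))`.
#' @return A data frame with one row per component and columns `name`,
#'   `system`, `threshold`, `direction`, `threshold_male`, `threshold_female`,
#'   and `anchors` (a list-column of character vectors; `character(0)` when
#'   no auxiliary information exists).
#' @export
ali_components <- function(overrides = NULL) {
  path <- system.file("extdata", "ali_components.tsv", package = "alivalid")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  tab$anchors <- lapply(tab$anchors, function(a) {
    if (is.na(a) || !nzchar(a)) character(0) else trimws(strsplit(a, ";")[[1]])
  })
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), !is.null(names(overrides)))
    for (nm in names(overrides)) {
      i <- match(nm, tab$name)
      if (is.na(i)) stop("unknown component in overrides: ", nm)
      for (f in names(overrides[[nm]])) {
        if (!f %in% names(tab)) stop("unknown field in overrides: ", f)
        if (f == "anchors") tab$anchors[[i]] <- overrides[[nm]][[f]]
        else tab[[f]][i] <- overrides[[nm]][[f]]
      }
    }
  }
  ok <- tab$direction %in% c("greater", "greater_equal", "less")
  if (!all(ok)) stop("invalid direction(s): ", paste(tab$direction[!ok], collapse = ", "))
  class(tab) <- c("ali_component_table", class(tab))
  tab
}

#' Names of the ten canonical ALI components
#' @return character vector of length 10, in canonical order.
#' @export
ali_component_names <- function() {
  c("sbp", "dbp", "bmi", "triglycerides", "cholesterol",
    "crp", "hba1c", "albumin", "creatinine_clearance", "homocysteine")
}

component_spec <- function(name, specs = ali_components()) {
  i <- match(name, specs$name)
  if (is.na(i)) stop("unknown component: ", name)
  specs[i, , drop = FALSE]
}

#' Discretize one measurement into an unhealthy/healthy ALI component
#'
#' Applies the component's clinical threshold: the indicator is 1 when the
#' measurement is on the unhealthy side, 0 otherwise, and `NA` when the
#' measurement is missing (missingness propagates; it is never counted as
#' healthy). Multiple measurements per patient should be reduced to their
#' mean before discretization.
#'
#' @param measurement numeric scalar or vector (NA = missing).
#' @param name component name (one of [ali_component_names()]).
#' @param sex `"male"` or `"female"`; required for components with
#'   sex-specific thresholds (creatinine clearance). May be a vector
#'   recycled against `measurement`.
#' @param specs component table from [ali_components()].
#' @return integer vector of 0/1/NA.
#' @export
discretize_component <- function(measurement, name, sex = NULL,
                                 specs = ali_components()) {
  sp <- component_spec(name, specs)
  n <- length(measurement)
  if (is.na(sp$threshold)) {
    # sex-specific thresholds
    if (is.null(sex)) stop("sex is required for component '", name, "'")
    sex <- rep_len(as.character(sex), n)
    bad <- !sex %in% c("male", "female")
    if (any(bad & !is.na(measurement))) stop("sex must be 'male' or 'female'")
    thr <- ifelse(sex == "male", sp$threshold_male, sp$threshold_female)
  } else {
    thr <- rep_len(sp$threshold, n)
  }
  out <- switch(sp$direction,
    greater       = as.integer(measurement > thr),
    greater_equal = as.integer(measurement >= thr),
    less          = as.integer(measurement < thr)
  )
  out
}

#' Compute the ALI as the proportion of non-missing unhealthy components
#'
#' The ALI of a patient is the number of components at unhealthy levels
#' divided by the number of non-missing components. Missing components are
#' excluded from numerator and denominator alike — counting them as zeros
#' would misclassify them as healthy.
#'
#' @param indicators numeric/integer vector of exactly ten 0/1/NA values.
#' @return list with `value` (proportion in `[0, 1]`) and `n_nonmissing`.
#'   Errors when all ten components are missing (the ALI is undefined, never
#'   silently zero).
#' @export
compute_ali <- function(indicators) {
  if (length(indicators) != 10L)
    stop("exactly ten component indicators are required, got ", length(indicators))
  if (!all(indicators %in% c(0L, 1L) | is.na(indicators)))
    stop("indicators must be 0, 1, or NA")
  obs <- !is.na(indicators)
  m <- sum(obs)
  if (m == 0L) stop("ALI is undefined: all ten components are missing")
  list(value = sum(indicators[obs]) / m, n_nonmissing = m)
}

#' Recover missing components from audit-roadmap auxiliary information
#'
#' During chart review, a missing component whose roadmap anchors (e.g., a
#' diabetes diagnosis for missing HbA1c) are found in the chart is treated as
#' unhealthy: the indicator becomes 1 and the component re-enters the ALI.
#' Recovery can only assign 1 — the roadmap defines auxiliary information for
#' presumed-unhealthy values only. Components without anchors (serum albumin)
#' can never be recovered.
#'
#' @param indicators ten 0/1/NA component indicators named by
#'   [ali_component_names()] (or in canonical order).
#' @param auxiliary_found named logical/0-1 vector over component names; may
#'   only flag components that are missing and have non-empty anchors.
#' @param specs component table from [ali_components()].
#' @return the updated indicator vector.
#' @export
apply_roadmap_recovery <- function(indicators, auxiliary_found,
                                   specs = ali_components()) {
  nms <- ali_component_names()
  if (is.null(names(indicators))) {
    stopifnot(length(indicators) == 10L)
    names(indicators) <- nms
  }
  if (length(auxiliary_found) == 0L) return(indicators)
  if (is.null(names(auxiliary_found)))
    stop("auxiliary_found must be named by component")
  for (nm in names(auxiliary_found)) {
    if (!as.logical(auxiliary_found[[nm]])) next
    i <- match(nm, specs$name)
    if (is.na(i)) stop("unknown component: ", nm)
    if (length(specs$anchors[[i]]) == 0L)
      stop("component '", nm, "' has no auxiliary anchors and cannot be recovered")
    if (!is.na(indicators[[nm]]))
      stop("auxiliary_found set for non-missing component '", nm, "'")
    indicators[[nm]] <- 1L
  }
  indicators
}
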