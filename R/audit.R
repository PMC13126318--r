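#' @title Chart-review audit bookkeeping
#' @description Long-format audit tables, the five mutually exclusive
#'   auditor finding categories, data-quality summaries (TPR, FPR, missing
#'   data recovery), and inter-auditor agreement.
#' @name audit_tools
NULL

audit_findings <- c("extracted_correct", "extracted_incorrect",
                    "extracted_not_found", "aux_found", "aux_not_found")

#' Transform a wide extraction table to the long audit format
#'
#' Chart reviewers work one value at a time, so the extracted EHR table
#' (one row per patient encounter, one column per variable) is reshaped to
#' one row per encounter per variable, with empty review columns for the
#' auditor to fill.
#'
#' @param wide data frame with `patient_id`, `encounter_id`, and one column
#'   per measured variable.
#' @param id_cols names of the identifier columns.
#' @return data frame with columns `patient_id`, `encounter_id`,
#'   `variable`, `extracted_value`, `reviewed_value` (empty), `finding`
#'   (empty), `notes` (empty).
#' @export
audit_long <- function(wide, id_cols = c("patient_id", "encounter_id")) {
  stopifnot(all(id_cols %in% names(wide)))
  vars <- setdiff(names(wide), id_cols)
  if (anyDuplicated(wide[id_cols]))
    stop("duplicate (patient, encounter) rows in the wide table")
  if (nrow(wide) == 0L || length(vars) == 0L)
    return(data.frame(patient_id = character(0), encounter_id = character(0),
                      variable = character(0), extracted_value = numeric(0),
                      reviewed_value = character(0), finding = character(0),
                      notes = character(0)))
  out <- do.call(rbind, lapply(vars, function(v)
    data.frame(patient_id = wide[[id_cols[1]]],
               encounter_id = wide[[id_cols[2]]],
               variable = v, extracted_value = as.numeric(wide[[v]]),
               reviewed_value = NA_character_, finding = NA_character_,
               notes = "")))
  out <- out[order(match(out$patient_id, wide[[id_cols[1]]]), out$variable), ]
  rownames(out) <- NULL
  out
}

#' Reshape a long audit table back to wide extracted values
#' @param long a long audit table from [audit_long()].
#' @return wide data frame of extracted values.
#' @export
audit_wide <- function(long) {
  wide <- stats::reshape(
    long[c("patient_id", "encounter_id", "variable", "extracted_value")],
    idvar = c("patient_id", "encounter_id"), timevar = "variable",
    direction = "wide")
  names(wide) <- sub("^extracted_value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Classify an audit entry into one of the five auditor findings
#'
#' For values that were *non-missing* in the extracted EHR data, the
#' reviewed value is compared against the extraction: equal (within
#' `tolerance`, default exact) is `extracted_correct`, unequal is
#' `extracted_incorrect`, and a review of `"not_found"` (the value could
#' not be located in the chart) is `extracted_not_found`. For *missing*
#' extracted values, the review records auxiliary information: any
#' non-empty text yields `aux_found`, an empty review yields
#' `aux_not_found`. The categories are mutually exclusive and exhaustive.
#'
#' @param extracted_value numeric vector (NA = missing in the EHR).
#' @param reviewed_value character vector: a number as text, `"not_found"`,
#'   auxiliary-information text, or `""`/NA for nothing found.
#' @param tolerance absolute tolerance for numeric agreement; the default 0
#'   means a transposed 5.6 vs 6.5 registers as incorrect.
#' @return character vector of findings.
#' @export
classify_finding <- function(extracted_value, reviewed_value, tolerance = 0) {
  n <- length(extracted_value)
  stopifnot(length(reviewed_value) == n)
  reviewed_value <- as.character(reviewed_value)
  out <- character(n)
  for (i in seq_len(n)) {
    ex <- extracted_value[i]; rv <- reviewed_value[i]
    empty <- is.na(rv) || !nzchar(trimws(rv))
    if (is.na(ex)) {
      if (!empty && identical(trimws(rv), "not_found"))
        stop("inconsistent entry ", i, ": extracted value is missing but the ",
             "review says 'not_found'")
      out[i] <- if (empty) "aux_not_found" else "aux_found"
    } else {
      if (empty)
        stop("inconsistent entry ", i, ": non-missing extracted value with ",
             "an empty review")
      if (identical(trimws(rv), "not_found")) out[i] <- "extracted_not_found"
      else {
        num <- suppressWarnings(as.numeric(rv))
        if (is.na(num))
          stop("entry ", i, ": reviewed value '", rv, "' is not numeric or ",
               "'not_found'")
        out[i] <- if (abs(num - ex) <= tolerance) "extracted_correct"
                  else "extracted_incorrect"
      }
    }
  }
  out
}

#' Summarize audit data quality: TPR, FPR, recovery, finding counts
#'
#' Two complementary inputs feed the summary. The long audit `entries`
#' (with `finding` filled, and optionally a `variable_class` column, e.g.
#' labs vs vitals) give the per-category counts and the missing-data
#' recovery rate `aux_found / (aux_found + aux_not_found)`. The optional
#' `components` table — one row per patient-component with discretized
#' `ehr` and `validated` indicators — gives the component-level error
#' rates: `TPR = P(ehr = 1 | validated = 1)` and
#' `FPR = P(ehr = 1 | validated = 0)`, both over components non-missing in
#' the EHR and with a validated value (entries classified
#' `extracted_not_found` carry no validated value and fall out of these
#' denominators).
#'
#' Every proportion is reported with its numerator and denominator; empty
#' denominators yield `NA` estimates with count 0 rather than an error.
#'
#' @param entries classified long audit table (or `NULL`).
#' @param components data frame with columns `ehr`, `validated` (0/1/NA)
#'   (or `NULL`).
#' @return list of class `ali_quality_summary` with `tpr`, `fpr`,
#'   `recovery`, `finding_counts`, and `by_class` when `variable_class`
#'   exists.
#' @export
quality_summary <- function(entries = NULL, components = NULL) {
  prop <- function(num, den)
    list(estimate = if (den > 0) num / den else NA_real_, num = num, den = den)
  out <- list(tpr = prop(0L, 0L), fpr = prop(0L, 0L), recovery = prop(0L, 0L),
              finding_counts = NULL, by_class = NULL)
  if (!is.null(entries)) {
    if (anyNA(entries$finding)) stop("entries must be classified first")
    bad <- setdiff(unique(entries$finding), audit_findings)
    if (length(bad)) stop("unknown finding(s): ", paste(bad, collapse = ", "))
    f <- factor(entries$finding, levels = audit_findings)
    out$finding_counts <- table(finding = f)
    out$recovery <- prop(sum(f == "aux_found"),
                         sum(f %in% c("aux_found", "aux_not_found")))
    if (!is.null(entries$variable_class))
      out$by_class <- table(class = entries$variable_class, finding = f)
  }
  if (!is.null(components)) {
    ok <- !is.na(components$ehr) & !is.na(components$validated)
    pos <- ok & components$validated == 1
    neg <- ok & components$validated == 0
    out$tpr <- prop(sum(components$ehr[pos] == 1), sum(pos))
    out$fpr <- prop(sum(components$ehr[neg] == 1), sum(neg))
  }
  class(out) <- "ali_quality_summary"
  out
}

#' @export
print.ali_quality_summary <- function(x, ...) {
  pct <- function(p) if (is.na(p$estimate)) "undefined (n=0)"
    else sprintf("%.1f%% (%d/%d)", 100 * p$estimate, p$num, p$den)
  cat("Audit data-quality summary\n")
  cat("  TPR:     ", pct(x$tpr), "\n")
  cat("  FPR:     ", pct(x$fpr), "\n")
  cat("  Recovery:", pct(x$recovery), "\n")
  if (!is.null(x$finding_counts)) { cat("  Findings:\n"); print(x$finding_counts) }
  invisible(x)
}

#' Fleiss' kappa for multi-rater agreement
#'
#' Chance-corrected agreement for `n_raters` raters assigning items to
#' nominal categories: `kappa = (Pbar - Pbar_e) / (1 - Pbar_e)` where
#' `Pbar` averages the per-item pairwise agreement and `Pbar_e` is the
#' agreement expected from the marginal category proportions.
#'
#' @param ratings items-by-categories matrix of counts; each row must sum
#'   to the same number of raters.
#' @return scalar kappa; 1 for perfect agreement. When every rating falls
#'   in a single category, chance agreement is 1 and kappa is undefined
#'   (`NA` with a warning).
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  n_raters <- unique(rowSums(ratings))
  if (length(n_raters) != 1L)
    stop("every item must be rated by the same number of raters")
  n <- n_raters[1]
  if (n < 2) stop("at least two raters are required")
  N <- nrow(ratings)
  P_i <- (rowSums(ratings^2) - n) / (n * (n - 1))
  p_j <- colSums(ratings) / (N * n)
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (abs(1 - Pe) < 1e-12) {
    warning("all ratings fall in one category; kappa is undefined")
    return(NA_real_)
  }
  (Pbar - Pe) / (1 - Pe)
}
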