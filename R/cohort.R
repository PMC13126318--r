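#' Configuration for the synthetic EHR cohort generator
#'
#' Describes the statistical world the downstream methods assume: a logistic
#' healthcare-utilization outcome in true ALI and age, component-level
#' misclassification (TPR/FPR), component-level missingness (optionally
#' dependent on the true component value), and audit-roadmap recovery of
#' missing unhealthy components at a configurable rate.
#'
#' Age is drawn uniformly on `age_range` and entered into the model as
#' `z = (age - 18) / 10`, so the intercept is the 18-year-old baseline and
#' the age coefficient is per decade of age.
#'
#' @param n_patients cohort size N.
#' @param beta length-3 log-odds coefficients `(b0, b1, b2)` of
#'   `logit Pr(Y=1) = b0 + b1*X + b2*Z`. Defaults correspond to baseline
#'   odds 0.23, OR 1.12 per 0.1 ALI, and OR 1.11 per decade of age.
#' @param age_range numeric length 2, in years.
#' @param prevalence named length-10 probabilities that each true component
#'   is unhealthy (`S_j = 1`).
#' @param prevalence_age_slope per-decade shift, on the logit scale, of each
#'   component prevalence (0 = age-independent).
#' @param tpr,fpr probability that a non-missing EHR component is recorded
#'   unhealthy given the true component is unhealthy (`tpr`) or healthy
#'   (`fpr`). A warning (not an error) is raised when `tpr < fpr`.
#' @param missingness named length-10 per-component probability that the EHR
#'   measurement is missing when the true component is healthy.
#' @param missingness_unhealthy optional length-10 missingness probabilities
#'   applying when the true component is unhealthy; `NULL` (default) copies
#'   `missingness`, i.e., missing completely at random within component.
#'   Setting these differently makes measurement informative (MNAR).
#' @param recovery_rate probability that chart review finds auxiliary
#'   information for a missing, truly unhealthy, recoverable component.
#' @param seed integer seed governing all randomness.
#' @param specs component table from [ali_components()].
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_patients = 1000,
                             beta = c(log(0.23), 10 * log(1.12), log(1.11)),
                             age_range = c(18, 65),
                             prevalence = default_prevalence(),
                             prevalence_age_slope = 0,
                             tpr = 1.00, fpr = 0.01,
                             missingness = default_missingness(),
                             missingness_unhealthy = NULL,
                             recovery_rate = 0.27,
                             seed = 1L,
                             specs = ali_components()) {
  nms <- ali_component_names()
  prevalence <- resolve_component_vector(prevalence, nms, "prevalence")
  missingness <- resolve_component_vector(missingness, nms, "missingness")
  if (is.null(missingness_unhealthy)) missingness_unhealthy <- missingness
  missingness_unhealthy <- resolve_component_vector(missingness_unhealthy, nms,
                                                    "missingness_unhealthy")
  if (n_patients < 1) stop("n_patients must be >= 1")
  stopifnot(length(beta) == 3, length(age_range) == 2)
  probs <- c(prevalence, missingness, missingness_unhealthy, tpr, fpr, recovery_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (tpr < fpr) warning("tpr < fpr: EHR components would be anti-correlated with truth")
  structure(list(
    n_patients = as.integer(n_patients), beta = as.numeric(beta),
    age_range = age_range, prevalence = prevalence,
    prevalence_age_slope = prevalence_age_slope,
    tpr = tpr, fpr = fpr, missingness = missingness,
    missingness_unhealthy = missingness_unhealthy,
    recovery_rate = recovery_rate, seed = as.integer(seed), specs = specs
  ), class = "generator_config")
}

# defaults chosen so the error-prone ALI is right-skewed with median near 1/3
# and a median of ~6 non-missing components per patient; see the methods
# vignette for the rationale
#' @rdname generator_config
#' @export
default_prevalence <- function() {
  c(sbp = 0.30, dbp = 0.15, bmi = 0.45, triglycerides = 0.35,
    cholesterol = 0.40, crp = 0.50, hba1c = 0.25, albumin = 0.15,
    creatinine_clearance = 0.50, homocysteine = 0.40)
}

#' @rdname generator_config
#' @export
default_missingness <- function() {
  c(sbp = 0.02, dbp = 0.02, bmi = 0.05, triglycerides = 0.30,
    cholesterol = 0.25, crp = 0.97, hba1c = 0.55, albumin = 0.50,
    creatinine_clearance = 0.45, homocysteine = 0.97)
}

resolve_component_vector <- function(x, nms, what) {
  if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(x, 10L), nms)
  if (is.null(names(x)) && length(x) == 10L) names(x) <- nms
  if (!setequal(names(x), nms))
    stop(what, " must be a single value or named over the ten components")
  as.numeric(x[nms])
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Generate a synthetic cohort of patients with error-prone ALI data
#'
#' For each patient: age is drawn; true components `S_j` are Bernoulli with
#' the configured (optionally age-dependent) prevalences; missingness flags
#' `M_j*` are drawn with probability depending on the true value when the
#' two missingness vectors differ; observed EHR components `S_j*` are drawn
#' from `S_j` via `tpr`/`fpr`; the true ALI `X` uses all ten true components
#' while the error-prone `X*` is the proportion over non-missing EHR
#' components; the outcome `Y` is Bernoulli with
#' `logit = b0 + b1*X + b2*Z`.
#'
#' In the rare event every component of a patient comes out missing, the
#' component with the lowest configured missingness is forced observed so
#' `X*` stays defined; this is deterministic given the seed.
#'
#' @param config a [generator_config()].
#' @return a data frame of class `ali_cohort`, one row per patient, with
#'   columns `id`, `age`, `z`, `y`, `x_true`, `x_star`, `n_star`, `v`,
#'   `x_validated`, `n_validated`, plus per-component columns
#'   `s_true_*`, `s_star_*` (NA = missing).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  nms <- ali_component_names()
  N <- config$n_patients
  with_seed(config$seed, {
    age <- stats::runif(N, config$age_range[1], config$age_range[2])
    z <- (age - 18) / 10
    s_true <- matrix(0L, N, 10L, dimnames = list(NULL, nms))
    for (j in seq_len(10L)) {
      pj <- stats::plogis(stats::qlogis(config$prevalence[j]) +
                            config$prevalence_age_slope * z)
      s_true[, j] <- stats::rbinom(N, 1L, pj)
    }
    # missingness may depend on the true component value (MNAR switch)
    m_prob <- matrix(config$missingness, N, 10L, byrow = TRUE)
    unhealthy <- s_true == 1L
    m_prob[unhealthy] <- matrix(config$missingness_unhealthy, N, 10L,
                                byrow = TRUE)[unhealthy]
    m_star <- matrix(stats::rbinom(N * 10L, 1L, as.vector(m_prob)), N, 10L,
                     dimnames = list(NULL, nms))
    all_missing <- rowSums(m_star) == 10L
    if (any(all_missing)) {
      j0 <- which.min(config$missingness)
      m_star[all_missing, j0] <- 0L
    }
    flip_p <- ifelse(s_true == 1L, config$tpr, config$fpr)
    s_star <- matrix(stats::rbinom(N * 10L, 1L, as.vector(flip_p)), N, 10L,
                     dimnames = list(NULL, nms))
    s_star[m_star == 1L] <- NA_integer_
    x_true <- rowMeans(s_true)
    n_star <- rowSums(!is.na(s_star))
    x_star <- rowSums(s_star == 1L, na.rm = TRUE) / n_star
    y <- stats::rbinom(N, 1L, stats::plogis(
      config$beta[1] + config$beta[2] * x_true + config$beta[3] * z))
    out <- data.frame(id = seq_len(N), age = age, z = z, y = y,
                      x_true = x_true, x_star = x_star, n_star = n_star,
                      v = 0L, x_validated = NA_real_,
                      n_validated = NA_integer_)
    colnames(s_true) <- paste0("s_true_", nms)
    colnames(s_star) <- paste0("s_star_", nms)
    out <- cbind(out, as.data.frame(s_true), as.data.frame(s_star))
    for (nm in nms) out[[paste0("s_val_", nm)]] <- NA_integer_
    attr(out, "generator_config") <- config
    class(out) <- c("ali_cohort", class(out))
    out
  })
}

#' Apply chart-review validation to selected patients
#'
#' Marks the selected patients validated (`v = 1`) and constructs their
#' validated components: originally non-missing EHR components are replaced
#' by the true components (chart review corrects extraction errors), and
#' each originally missing component that is truly unhealthy and has
#' roadmap anchors is revealed as unhealthy with probability
#' `recovery_rate`. Missing healthy components, and missing components with
#' no anchors (serum albumin), stay missing — the roadmap only covers
#' presumed-unhealthy values. The validated ALI is recomputed as the
#' proportion over post-validation non-missing components.
#'
#' @param cohort an `ali_cohort`.
#' @param selected_ids distinct patient ids present in the cohort.
#' @param config the cohort's [generator_config()] (defaults to the one
#'   attached to the cohort); supplies `recovery_rate` and the component
#'   specs.
#' @param seed optional seed for the recovery draws (defaults to
#'   `config$seed + 1`).
#' @return the cohort with `v`, `x_validated`, `n_validated`, and the
#'   `s_val_*` columns filled for the selected patients.
#' @export
apply_validation <- function(cohort, selected_ids,
                             config = attr(cohort, "generator_config"),
                             seed = NULL) {
  stopifnot(inherits(cohort, "ali_cohort"), !is.null(config))
  if (anyDuplicated(selected_ids)) stop("selected_ids contains repeats")
  rows <- match(selected_ids, cohort$id)
  if (anyNA(rows)) stop("unknown id(s): ",
                        paste(selected_ids[is.na(rows)], collapse = ", "))
  nms <- ali_component_names()
  recoverable <- vapply(nms, function(nm)
    length(config$specs$anchors[[match(nm, config$specs$name)]]) > 0, logical(1))
  if (is.null(seed)) seed <- config$seed + 1L
  with_seed(seed, {
    s_true <- as.matrix(cohort[rows, paste0("s_true_", nms), drop = FALSE])
    s_star <- as.matrix(cohort[rows, paste0("s_star_", nms), drop = FALSE])
    # chart review corrects errors in non-missing components
    s_val <- ifelse(is.na(s_star), NA_integer_, s_true)
    miss_unhealthy <- is.na(s_star) & s_true == 1L &
      matrix(recoverable, nrow(s_true), 10L, byrow = TRUE)
    idx <- which(miss_unhealthy)
    if (length(idx)) {
      found <- stats::rbinom(length(idx), 1L, config$recovery_rate) == 1L
      s_val[idx[found]] <- 1L
    }
    n_val <- rowSums(!is.na(s_val))
    if (any(n_val == 0L))
      stop("ALI is undefined after validation for id(s): ",
           paste(selected_ids[n_val == 0L], collapse = ", "))
    for (k in seq_along(nms))
      cohort[[paste0("s_val_", nms[k])]][rows] <- s_val[, k]
    cohort$x_validated[rows] <- rowSums(s_val == 1L, na.rm = TRUE) / n_val
    cohort$n_validated[rows] <- n_val
    cohort$v[rows] <- 1L
    cohort
  })
}

#' Empirical component-level error and recovery rates of a cohort
#'
#' Compares the error-prone components to the true ones over all patients:
#' TPR/FPR among non-missing components and, when validated rows exist, the
#' realized recovery proportion among originally-missing truly-unhealthy
#' recoverable components.
#'
#' @param cohort an `ali_cohort`.
#' @return list with `tpr`, `fpr` (each with `estimate`, `num`, `den`).
#' @export
empirical_error_rates <- function(cohort) {
  nms <- ali_component_names()
  s_true <- as.matrix(cohort[paste0("s_true_", nms)])
  s_star <- as.matrix(cohort[paste0("s_star_", nms)])
  obs <- !is.na(s_star)
  pos <- obs & s_true == 1L
  neg <- obs & s_true == 0L
  list(
    tpr = list(estimate = sum(s_star[pos] == 1L) / sum(pos),
               num = sum(s_star[pos] == 1L), den = sum(pos)),
    fpr = list(estimate = sum(s_star[neg] == 1L) / sum(neg),
               num = sum(s_star[neg] == 1L), den = sum(neg))
  )
}
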