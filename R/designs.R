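#' @title Validation sampling designs
#' @description Strategies to pick which patients get chart-reviewed in a
#'   two-phase validation study. All strategies operate on fully observed
#'   phase-I data `(Y, X*, Z)` only — never on the true ALI — so validated
#'   ALI is missing at random by construction for every design here.
#' @name validation_designs
NULL

eligible_rows <- function(cohort, exclude_ids = integer(0)) {
  which(cohort$v == 0L & !(cohort$id %in% exclude_ids))
}

design_result <- function(ids, strategy, n, wave_label = strategy,
                          per_stratum_counts = NULL, residuals = NULL,
                          params = list()) {
  if (anyDuplicated(ids)) stop("internal: duplicate ids selected")
  structure(list(selected_ids = as.integer(ids), strategy = strategy,
                 n = as.integer(n), wave_label = wave_label,
                 per_stratum_counts = per_stratum_counts,
                 residuals = residuals, params = params),
            class = "ali_design")
}

#' @export
print.ali_design <- function(x, ...) {
  cat("Validation design:", x$strategy, "| wave:", x$wave_label,
      "| n =", length(x$selected_ids), "\n")
  if (!is.null(x$per_stratum_counts)) {
    cat("Per-stratum allocation:\n")
    print(x$per_stratum_counts)
  }
  invisible(x)
}

#' Simple random sampling (SRS) of patients for validation
#'
#' Every eligible (not previously validated) patient is chosen with equal
#' probability, without replacement.
#'
#' @param cohort an `ali_cohort`.
#' @param n number of patients to select.
#' @param seed integer seed.
#' @param exclude_ids ids never to select (e.g., earlier waves).
#' @return an `ali_design` with `selected_ids`.
#' @export
sample_srs <- function(cohort, n, seed = 1L, exclude_ids = integer(0)) {
  rows <- eligible_rows(cohort, exclude_ids)
  if (n > length(rows)) stop("n exceeds the number of eligible patients")
  ids <- with_seed(seed, cohort$id[sample(rows, n)])
  design_result(ids, "srs", n, params = list(seed = seed))
}

#' Stratum rules for case-control style designs
#'
#' `strata_cc` stratifies on the outcome Y alone; `strata_bcc` further
#' splits on the error-prone ALI discretized at `cutpoint` (default: the
#' within-cohort median of `X*`), giving four `(Y, X*_D)` strata. Model
#' fitting still uses the continuous `X*`.
#'
#' @param cohort an `ali_cohort`.
#' @param cutpoint threshold for `X*` discretization.
#' @return a factor over the cohort rows.
#' @export
strata_cc <- function(cohort) factor(cohort$y, levels = c(0, 1),
                                     labels = c("Y=0", "Y=1"))

#' @rdname strata_cc
#' @export
strata_bcc <- function(cohort, cutpoint = stats::median(cohort$x_star)) {
  xd <- ifelse(cohort$x_star > cutpoint, "hi", "lo")
  interaction(strata_cc(cohort), factor(xd, levels = c("lo", "hi")),
              sep = ",X*=", drop = FALSE)
}

# split n as evenly as possible over strata; remainder goes to the larger
# strata first (ties by label order)
equal_allocation <- function(n, sizes) {
  H <- length(sizes)
  base <- rep(n %/% H, H)
  rem <- n %% H
  if (rem > 0) {
    ord <- order(-sizes, seq_len(H))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  stats::setNames(base, names(sizes))
}

# cap allocation at stratum sizes, redistributing shortfall proportionally
# to remaining capacity
redistribute_allocation <- function(alloc, sizes) {
  repeat {
    over <- alloc > sizes
    if (!any(over)) return(alloc)
    excess <- sum(alloc[over] - sizes[over])
    alloc[over] <- sizes[over]
    room <- sizes - alloc
    if (sum(room) < excess)
      stop("allocation infeasible: not enough eligible patients in strata")
    open <- which(room > 0)
    add <- floor(excess * room[open] / sum(room[open]))
    short <- excess - sum(add)
    if (short > 0) {
      ord <- open[order(-room[open])]
      add[match(ord[seq_len(short)], open)] <-
        add[match(ord[seq_len(short)], open)] + 1L
    }
    alloc[open] <- alloc[open] + add
  }
}

#' Stratified random sampling with an explicit allocation
#'
#' Performs an independent simple random sample within each stratum at the
#' allocated sizes. Strata with allocation exceeding their size are taken
#' whole and the shortfall is redistributed proportionally to the remaining
#' capacity of other strata.
#'
#' @param cohort an `ali_cohort`.
#' @param strata a factor over cohort rows (see [strata_cc()],
#'   [strata_bcc()]), or a function `cohort -> factor`.
#' @param allocation named integer vector of per-stratum sample sizes, or a
#'   single total `n` to split equally across strata.
#' @param seed integer seed.
#' @param strategy label recorded in the result.
#' @inheritParams sample_srs
#' @return an `ali_design` with `per_stratum_counts`.
#' @export
sample_stratified <- function(cohort, strata, allocation, seed = 1L,
                              exclude_ids = integer(0), strategy = "stratified") {
  if (is.function(strata)) strata <- strata(cohort)
  stopifnot(length(strata) == nrow(cohort))
  rows <- eligible_rows(cohort, exclude_ids)
  st <- droplevels(factor(strata[rows]))
  sizes <- stats::setNames(as.integer(table(st)), levels(st))
  if (length(allocation) == 1L && is.null(names(allocation))) {
    if (allocation > length(rows)) stop("n exceeds the number of eligible patients")
    alloc <- equal_allocation(as.integer(allocation), sizes)
  } else {
    if (!setequal(names(allocation), names(sizes)))
      stop("allocation names must match the (non-empty) strata: ",
           paste(names(sizes), collapse = ", "))
    alloc <- as.integer(allocation[names(sizes)])
    names(alloc) <- names(sizes)
  }
  alloc <- redistribute_allocation(alloc, sizes)
  ids <- with_seed(seed, {
    unlist(lapply(names(sizes), function(h) {
      rh <- rows[st == h]
      if (alloc[h] == 0L) integer(0)
      else cohort$id[rh[sample.int(length(rh), alloc[h])]]
    }))
  })
  design_result(ids, strategy, sum(alloc), per_stratum_counts = alloc,
                params = list(seed = seed))
}

#' Case-control and balanced case-control designs
#'
#' `sample_cc` selects equal numbers of patients with `Y = 0` and `Y = 1`;
#' `sample_bcc` selects equal numbers from the four `(Y, X*_D)` strata with
#' `X*` discretized at `cutpoint`.
#'
#' @inheritParams sample_stratified
#' @param n total number of patients to select.
#' @param cutpoint threshold used by [strata_bcc()].
#' @export
sample_cc <- function(cohort, n, seed = 1L, exclude_ids = integer(0)) {
  sample_stratified(cohort, strata_cc(cohort), n, seed, exclude_ids, "cc")
}

#' @rdname sample_cc
#' @export
sample_bcc <- function(cohort, n, cutpoint = stats::median(cohort$x_star),
                       seed = 1L, exclude_ids = integer(0)) {
  d <- sample_stratified(cohort, strata_bcc(cohort, cutpoint), n, seed,
                         exclude_ids, "bcc")
  d$params$cutpoint <- cutpoint
  d
}

#' Residuals of the naive healthcare-utilization model
#'
#' `r_i = Y_i - expit(b0 + b1*X*_i + b2*Z_i)`: the gap between each
#' patient's observed outcome and the probability the naive (error-prone)
#' logistic model predicts for it. Patients with extreme residuals are the
#' ones the naive model explains worst, hence the most informative to
#' validate.
#'
#' @param cohort an `ali_cohort`.
#' @param beta_naive length-3 coefficients of the naive model.
#' @return numeric vector of per-patient residuals.
#' @export
compute_residuals <- function(cohort, beta_naive) {
  stopifnot(length(beta_naive) == 3)
  if (anyNA(cohort$x_star) || anyNA(cohort$z))
    stop("x_star and z must be non-missing for all patients")
  cohort$y - stats::plogis(beta_naive[1] + beta_naive[2] * cohort$x_star +
                             beta_naive[3] * cohort$z)
}

# deterministic two-tail pick by a ranking value; ties at a selection
# boundary are resolved by a seeded uniform draw among the tied patients
pick_tails <- function(values, rows, n_low, n_high, seed) {
  take_tail <- function(v, k, decreasing) {
    if (k == 0L) return(integer(0))
    ord <- order(v, decreasing = decreasing)
    cut <- v[ord[k]]
    sure <- if (decreasing) which(v > cut) else which(v < cut)
    tied <- which(v == cut)
    need <- k - length(sure)
    if (length(tied) > need) tied <- tied[sample.int(length(tied), need)]
    c(sure, tied)
  }
  with_seed(seed, {
    low <- take_tail(values, n_low, decreasing = FALSE)
    remaining <- setdiff(seq_along(values), low)
    vh <- values[remaining]
    high <- remaining[take_tail(vh, n_high, decreasing = TRUE)]
    rows[c(low, high)]
  })
}

#' Residual sampling (RS)
#'
#' Ranks eligible patients by their naive-model residuals and selects the
#' `n/2` most negative and `n/2` most positive. For odd `n` the extra
#' patient goes to the side with the larger absolute extreme residual.
#'
#' @inheritParams sample_srs
#' @param beta_naive length-3 naive logistic coefficients (see
#'   [fit_naive()]); residuals are recomputed from them.
#' @export
sample_rs <- function(cohort, n, beta_naive, seed = 1L,
                      exclude_ids = integer(0)) {
  rows <- eligible_rows(cohort, exclude_ids)
  if (n > length(rows)) stop("n exceeds the number of eligible patients")
  r_all <- compute_residuals(cohort, beta_naive)
  r <- r_all[rows]
  n_low <- n %/% 2L; n_high <- n %/% 2L
  if (n %% 2L == 1L) {
    if (abs(min(r)) >= abs(max(r))) n_low <- n_low + 1L else n_high <- n_high + 1L
  }
  sel <- pick_tails(r, rows, n_low, n_high, seed)
  design_result(cohort$id[sel], "rs", n, residuals = r_all,
                params = list(beta_naive = beta_naive, seed = seed))
}

#' Extreme tail sampling (ETS)
#'
#' Orders eligible patients by a fully observed column (default the
#' error-prone ALI `x_star`) and selects the two extremes, split as in
#' [sample_rs()].
#'
#' @inheritParams sample_srs
#' @param rank_value name of the cohort column to rank on.
#' @export
sample_ets <- function(cohort, n, rank_value = "x_star", seed = 1L,
                       exclude_ids = integer(0)) {
  if (rank_value %in% c("x_true", "x_validated"))
    stop("ranking on ", rank_value, " would break the MAR-by-design guarantee")
  rows <- eligible_rows(cohort, exclude_ids)
  if (n > length(rows)) stop("n exceeds the number of eligible patients")
  vals <- cohort[[rank_value]][rows]
  n_low <- n %/% 2L
  sel <- pick_tails(vals, rows, n_low, n - n_low, seed)
  design_result(cohort$id[sel], "ets", n,
                params = list(rank_value = rank_value, seed = seed))
}
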