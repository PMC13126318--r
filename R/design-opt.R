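#' @title Optimal stratified validation design
#' @description Chooses the per-stratum allocation of validation slots that
#'   minimizes an approximation to the asymptotic variance of the ALI
#'   log-odds-ratio, then samples within strata. The variance approximation
#'   uses pilot values of the outcome-model coefficients and of the EHR
#'   error rates; the allocation search is exhaustive (steps of 1) and is
#'   limited to at most four strata.
#' @name optimal_design
NULL

# Approximate error mechanism Pr(X = x_k | X*) used only for design
# planning. Each of the 10 components independently disagrees between truth
# and EHR with probability err = (1 - tpr) * prev + fpr * (1 - prev); the
# number of disagreements D ~ Binomial(10, err) shifts X away from X* by
# D/10, half the mass in each direction, clipped to [0, 1] and snapped to
# the grid. Returns a K x K transition matrix indexed by snapped X*.
opt_transition_matrix <- function(grid, err) {
  K <- length(grid)
  T_ <- matrix(0, K, K)
  wd <- stats::dbinom(0:10, 10, err)
  snap <- function(x) which.min(abs(grid - x))
  for (ks in seq_len(K)) {
    for (d in 0:10) {
      if (wd[d + 1] < 1e-12) next
      if (d == 0) {
        T_[ks, ks] <- T_[ks, ks] + wd[1]
      } else {
        up <- snap(min(1, grid[ks] + d / 10))
        dn <- snap(max(0, grid[ks] - d / 10))
        T_[ks, up] <- T_[ks, up] + wd[d + 1] / 2
        T_[ks, dn] <- T_[ks, dn] + wd[d + 1] / 2
      }
    }
  }
  T_ / rowSums(T_)
}

# Per-patient incomplete-data observed information and information gain
# from validation, via Louis' missing-information identity: the gain of
# validating a patient equals the posterior variance of the complete-data
# score given (Y, X*, Z).
opt_information_parts <- function(cohort, beta, q, grid) {
  N <- nrow(cohort)
  K <- length(grid)
  eta <- outer(rep(beta[1], N) + beta[3] * cohort$z, beta[2] * grid, `+`)
  mu <- stats::plogis(eta)
  lik <- ifelse(matrix(cohort$y, N, K) == 1, mu, 1 - mu)
  w <- lik * q
  w <- w / pmax(rowSums(w), 1e-300)
  inc <- vector("list", N); gain <- vector("list", N)
  for (i in seq_len(N)) {
    ci <- rbind(1, grid, cohort$z[i])             # 3 x K
    si <- ci * rep(cohort$y[i] - mu[i, ], each = 3)
    wi <- w[i, ]
    Icomp <- (ci * rep(wi * mu[i, ] * (1 - mu[i, ]), each = 3)) %*% t(ci)
    sbar <- si %*% wi
    Vs <- (si * rep(wi, each = 3)) %*% t(si) - sbar %*% t(sbar)
    inc[[i]] <- Icomp - Vs
    gain[[i]] <- Vs
  }
  list(inc = inc, gain = gain)
}

enumerate_allocations <- function(n, caps) {
  H <- length(caps)
  if (H == 1L) return(matrix(min(n, caps), 1, 1))
  recurse <- function(h, left) {
    if (h == H) {
      if (left <= caps[H]) return(matrix(left, 1, 1)) else return(NULL)
    }
    out <- list()
    for (k in 0:min(left, caps[h])) {
      sub <- recurse(h + 1L, left - k)
      if (!is.null(sub)) out[[length(out) + 1L]] <- cbind(k, sub)
    }
    do.call(rbind, out)
  }
  m <- recurse(1L, n)
  if (is.null(m)) stop("no feasible allocation")
  m
}

#' Optimal (OPT) stratified design
#'
#' Allocates `n` validation slots across the strata to minimize the
#' approximate asymptotic variance of the ALI coefficient, then draws a
#' simple random sample within each stratum. The variance of an allocation
#' is `[solve(I0 + sum_h n_h * Gbar_h)]_{22}` where `I0` is the total
#' observed information of the incomplete (phase-I) data at the pilot
#' coefficients, and `Gbar_h` is the average per-patient information gained
#' by validating a stratum-`h` patient (the posterior variance of the
#' complete-data score). Ties are broken toward the most balanced
#' allocation.
#'
#' @inheritParams sample_srs
#' @param pilot_beta length-3 pilot coefficients (e.g., a naive fit).
#' @param pilot_error_rates list with `tpr`, `fpr`, and optionally `prev`
#'   (marginal component prevalence, default 1/3), or a list with a single
#'   `err` entry giving the per-component disagreement probability.
#' @param strata factor over cohort rows or function `cohort -> factor`;
#'   default [strata_bcc()]. At most four non-empty strata.
#' @param grid support grid for the planning error model.
#' @return an `ali_design` with `per_stratum_counts`.
#' @export
sample_opt <- function(cohort, n, pilot_beta, pilot_error_rates,
                       strata = strata_bcc, seed = 1L,
                       exclude_ids = integer(0), grid = ali_grid()) {
  if (missing(pilot_beta) || is.null(pilot_beta) ||
      missing(pilot_error_rates) || is.null(pilot_error_rates))
    stop("pilot_beta and pilot_error_rates are required for the OPT design")
  stopifnot(length(pilot_beta) == 3)
  if (!is.null(pilot_error_rates$err)) err <- pilot_error_rates$err
  else {
    prev <- if (is.null(pilot_error_rates$prev)) 1 / 3 else pilot_error_rates$prev
    err <- (1 - pilot_error_rates$tpr) * prev + pilot_error_rates$fpr * (1 - prev)
  }
  if (is.function(strata)) strata <- strata(cohort)
  rows <- eligible_rows(cohort, exclude_ids)
  if (n > length(rows)) stop("n exceeds the number of eligible patients")
  st <- droplevels(factor(strata[rows]))
  sizes <- stats::setNames(as.integer(table(st)), levels(st))
  H <- length(sizes)
  if (H > 4L) stop("exhaustive OPT search supports at most 4 strata")

  T_ <- opt_transition_matrix(grid, max(err, 1e-6))
  idx <- vapply(cohort$x_star, function(x) which.min(abs(grid - x)), integer(1))
  q <- T_[idx, , drop = FALSE]
  parts <- opt_information_parts(cohort, pilot_beta, q, grid)

  I0 <- Reduce(`+`, parts$inc[rows])
  # previously validated patients contribute complete-data information
  vrows <- which(cohort$v == 1L)
  for (i in vrows) {
    ci <- c(1, cohort$x_validated[i], cohort$z[i])
    mu <- stats::plogis(sum(pilot_beta * ci))
    I0 <- I0 + mu * (1 - mu) * (ci %*% t(ci))
  }
  Gbar <- lapply(levels(st), function(h)
    Reduce(`+`, parts$gain[rows[st == h]]) / sizes[[h]])

  allocs <- enumerate_allocations(as.integer(n), sizes)
  vars <- apply(allocs, 1L, function(a) {
    M <- I0
    for (h in seq_len(H)) M <- M + a[h] * Gbar[[h]]
    v <- tryCatch(solve(M)[2, 2], error = function(e) Inf)
    if (v <= 0) Inf else v
  })
  best <- min(vars)
  cand <- which(vars <= best * (1 + 1e-9))
  if (length(cand) > 1L) {
    imbalance <- rowSums(abs(allocs[cand, , drop = FALSE] - n / H))
    cand <- cand[order(imbalance, cand)]
  }
  alloc <- stats::setNames(allocs[cand[1L], ], names(sizes))
  d <- sample_stratified(cohort, strata, alloc, seed, exclude_ids, "opt")
  d$params <- c(d$params, list(pilot_beta = pilot_beta, err = err,
                               variance = best))
  d
}

#' Run several validation waves, never reselecting a patient
#'
#' Applies a sequence of design specifications, excluding from each wave's
#' eligible pool everyone selected in earlier waves (and anyone already
#' validated in the cohort). Rank-based waves recompute their inputs — the
#' naive coefficients for RS are refit from the current cohort unless
#' supplied in the wave spec.
#'
#' @param cohort an `ali_cohort`.
#' @param wave_specs list of lists with entries `strategy` (one of
#'   `"srs"`, `"cc"`, `"bcc"`, `"opt"`, `"ets"`, `"rs"`), `n`, `seed`, and
#'   optionally `label`, `cutpoint`, `rank_value`, `beta_naive`,
#'   `pilot_beta`, `pilot_error_rates`.
#' @return list of `ali_design`, one per wave; selections are disjoint.
#' @export
run_multiwave <- function(cohort, wave_specs) {
  taken <- integer(0)
  out <- vector("list", length(wave_specs))
  for (w in seq_along(wave_specs)) {
    ws <- wave_specs[[w]]
    stopifnot(!is.null(ws$strategy), !is.null(ws$n))
    seed <- if (is.null(ws$seed)) w else ws$seed
    label <- if (is.null(ws$label)) paste0("wave", w) else ws$label
    d <- switch(ws$strategy,
      srs = sample_srs(cohort, ws$n, seed, exclude_ids = taken),
      cc  = sample_cc(cohort, ws$n, seed, exclude_ids = taken),
      bcc = sample_bcc(cohort, ws$n,
                       cutpoint = if (is.null(ws$cutpoint))
                         stats::median(cohort$x_star) else ws$cutpoint,
                       seed = seed, exclude_ids = taken),
      ets = sample_ets(cohort, ws$n,
                       rank_value = if (is.null(ws$rank_value)) "x_star"
                                    else ws$rank_value,
                       seed = seed, exclude_ids = taken),
      rs  = {
        b <- if (is.null(ws$beta_naive)) fit_naive(cohort)$beta else ws$beta_naive
        sample_rs(cohort, ws$n, b, seed, exclude_ids = taken)
      },
      opt = sample_opt(cohort, ws$n, ws$pilot_beta, ws$pilot_error_rates,
                       seed = seed, exclude_ids = taken),
      stop("unknown strategy: ", ws$strategy)
    )
    d$wave_label <- label
    if (length(intersect(d$selected_ids, taken)))
      stop("internal: wave reselected a validated patient")
    taken <- c(taken, d$selected_ids)
    out[[w]] <- d
  }
  out
}
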