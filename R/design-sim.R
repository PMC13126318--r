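#' Define a design-comparison scenario grid
#'
#' Describes the simulation study used to pick the next validation wave's
#' design: data-quality scenarios (component error rates crossed with
#' missing-data recovery rates), the candidate designs, and the Monte Carlo
#' size. Cohorts are shared across designs within a replicate (common
#' random numbers), sharpening the variance comparison between designs.
#'
#' @param base_config a [generator_config()] giving the cohort model; its
#'   `tpr`, `fpr`, `recovery_rate`, and `seed` are overridden per scenario.
#' @param designs named list of design specs, each a list with `strategy`
#'   (`"srs"`, `"cc"`, `"bcc"`, `"opt"`, `"ets"`, `"rs"`), `n`, and any
#'   strategy-specific options.
#' @param error_levels list of `c(tpr, fpr)` pairs.
#' @param recovery_levels numeric vector of recovery rates.
#' @param n_reps Monte Carlo replicates per scenario (>= 2).
#' @param seed master seed; all per-replicate seeds derive from it.
#' @return a `scenario_grid` list.
#' @export
scenario_grid <- function(base_config, designs,
                          error_levels = list(c(tpr = 1.00, fpr = 0.01)),
                          recovery_levels = 0.9,
                          n_reps = 100, seed = 1L) {
  stopifnot(inherits(base_config, "generator_config"),
            length(designs) >= 1, length(error_levels) >= 1,
            length(recovery_levels) >= 1, n_reps >= 2)
  if (is.null(names(designs)))
    names(designs) <- vapply(designs, `[[`, "", "strategy")
  structure(list(base_config = base_config, designs = designs,
                 error_levels = error_levels,
                 recovery_levels = recovery_levels,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "scenario_grid")
}

select_by_spec <- function(cohort, spec, seed, naive_beta) {
  switch(spec$strategy,
    srs = sample_srs(cohort, spec$n, seed),
    cc  = sample_cc(cohort, spec$n, seed),
    bcc = sample_bcc(cohort, spec$n,
                     cutpoint = if (is.null(spec$cutpoint))
                       stats::median(cohort$x_star) else spec$cutpoint,
                     seed = seed),
    ets = sample_ets(cohort, spec$n,
                     rank_value = if (is.null(spec$rank_value)) "x_star"
                                  else spec$rank_value, seed = seed),
    rs  = sample_rs(cohort, spec$n, naive_beta, seed),
    opt = sample_opt(cohort, spec$n,
                     pilot_beta = if (is.null(spec$pilot_beta)) naive_beta
                                  else spec$pilot_beta,
                     pilot_error_rates = spec$pilot_error_rates, seed = seed),
    stop("unknown strategy: ", spec$strategy))
}

#' Run the design-comparison simulation
#'
#' For every scenario and replicate: generate a cohort, apply each
#' candidate design to the *same* cohort, validate the selected patients,
#' fit the sieve MLE, and record the ALI coefficient. Summaries report the
#' empirical mean, bias, SD, Monte Carlo SE, and relative efficiency
#' against SRS (variance ratio) per scenario-design cell; failed fits are
#' excluded and counted. The naive estimator is recorded alongside as the
#' `"naive"` row of each scenario.
#'
#' @param grid a [scenario_grid()].
#' @param smle_args list of extra arguments passed to [fit_smle()].
#' @param verbose print progress.
#' @return an `ali_sim_summary`: `summary` data frame, raw `estimates`, and
#'   the grid.
#' @export
run_design_comparison <- function(grid, smle_args = list(), verbose = FALSE) {
  stopifnot(inherits(grid, "scenario_grid"))
  scen <- expand.grid(err = seq_along(grid$error_levels),
                      rec = seq_along(grid$recovery_levels))
  n_scen <- nrow(scen)
  n_des <- length(grid$designs)
  R <- grid$n_reps
  seeds <- with_seed(grid$seed,
    matrix(sample.int(.Machine$integer.max - 1L, n_scen * R * (n_des + 1L)),
           nrow = n_scen * R))
  est <- array(NA_real_, dim = c(n_scen, n_des + 1L, R),
               dimnames = list(NULL, c(names(grid$designs), "naive"), NULL))
  true_b1 <- grid$base_config$beta[2]
  rows <- list()
  for (s in seq_len(n_scen)) {
    el <- grid$error_levels[[scen$err[s]]]
    rec <- grid$recovery_levels[scen$rec[s]]
    cfg <- grid$base_config
    cfg$tpr <- unname(el[1]); cfg$fpr <- unname(el[2]); cfg$recovery_rate <- rec
    for (r in seq_len(R)) {
      srow <- (s - 1L) * R + r
      cfg$seed <- seeds[srow, 1L]
      cohort <- generate_cohort(cfg)
      naive <- fit_naive(cohort)
      est[s, "naive", r] <- naive$beta[2]
      for (d in seq_len(n_des)) {
        spec <- grid$designs[[d]]
        ds <- seeds[srow, d + 1L]
        b1 <- tryCatch({
          sel <- select_by_spec(cohort, spec, ds, naive$beta)
          vc <- apply_validation(cohort, sel$selected_ids, cfg, seed = ds + 1L)
          fit <- do.call(fit_smle, c(list(cohort = vc, se = FALSE), smle_args))
          if (!fit$converged) NA_real_ else unname(fit$beta[2])
        }, error = function(e) NA_real_)
        est[s, d, r] <- b1
      }
      if (verbose && r %% 25 == 0)
        message("scenario ", s, "/", n_scen, " rep ", r, "/", R)
    }
    sd_srs <- if ("srs" %in% names(grid$designs))
      stats::sd(est[s, "srs", ], na.rm = TRUE) else NA_real_
    for (d in c(names(grid$designs), "naive")) {
      e <- est[s, d, ]
      ok <- sum(!is.na(e))
      rows[[length(rows) + 1L]] <- data.frame(
        tpr = unname(el[1]), fpr = unname(el[2]), recovery = rec, design = d,
        n_ok = ok, n_fail = R - ok,
        mean = mean(e, na.rm = TRUE), bias = mean(e, na.rm = TRUE) - true_b1,
        sd = stats::sd(e, na.rm = TRUE),
        mcse = stats::sd(e, na.rm = TRUE) / sqrt(ok),
        re_vs_srs = if (!is.na(sd_srs) && d != "naive")
          stats::var(e, na.rm = TRUE) / sd_srs^2 else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$n_ok == 0))
    warning("all replicates failed in ", sum(out$n_ok == 0), " cell(s)")
  structure(list(summary = out, estimates = est, grid = grid,
                 true_beta1 = true_b1),
            class = "ali_sim_summary")
}

#' Recommend the next wave's validation design
#'
#' Picks, in the scenario closest to the observed pilot error rates
#' (Euclidean distance over `(tpr, fpr, recovery)` on the probability
#' scale), the design minimizing the chosen criterion: empirical SD of the
#' ALI coefficient (default) or absolute empirical bias. Ties are broken
#' toward the design with the fewest assumptions (SRS first, then CC, BCC,
#' ETS, RS, OPT).
#'
#' @param sim an `ali_sim_summary` from [run_design_comparison()].
#' @param pilot_error_rates list with `tpr`, `fpr`, `recovery`; `NULL`
#'   requires a single-scenario summary.
#' @param criterion `"min_variance"` or `"min_bias"`.
#' @return list with `design` (the matching spec from the grid), `name`,
#'   and the matched `scenario` row.
#' @export
recommend_design <- function(sim, pilot_error_rates = NULL,
                             criterion = c("min_variance", "min_bias")) {
  criterion <- match.arg(criterion)
  s <- sim$summary[sim$summary$design != "naive" & sim$summary$n_ok > 0, ]
  if (nrow(s) == 0) stop("empty summary: no successful design cells")
  scens <- unique(s[c("tpr", "fpr", "recovery")])
  if (is.null(pilot_error_rates)) {
    if (nrow(scens) > 1)
      stop("pilot_error_rates required with more than one scenario")
    pick <- scens[1, ]
  } else {
    d2 <- (scens$tpr - pilot_error_rates$tpr)^2 +
      (scens$fpr - pilot_error_rates$fpr)^2 +
      (scens$recovery - pilot_error_rates$recovery)^2
    pick <- scens[which.min(d2), ]
  }
  cell <- s[s$tpr == pick$tpr & s$fpr == pick$fpr &
              s$recovery == pick$recovery, ]
  score <- if (criterion == "min_variance") cell$sd else abs(cell$bias)
  pref <- match(cell$design, c("srs", "cc", "bcc", "ets", "rs", "opt"))
  cell <- cell[order(score, pref), ]
  name <- cell$design[1]
  list(design = sim$grid$designs[[name]], name = name, scenario = pick,
       criterion = criterion)
}
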