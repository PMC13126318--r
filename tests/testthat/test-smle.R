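expit_ <- function(x) 1 / (1 + exp(-x))

# independent arithmetic oracle for the observed-data log-likelihood:
# plain double loop over patients and grid points
loglik_oracle <- function(beta, p, cohort, grid, basis) {
  B <- basis_matrix(basis, cohort$x_star, cohort$z)
  ll <- 0
  for (i in seq_len(nrow(cohort))) {
    q_i <- as.numeric(B[i, , drop = FALSE] %*% t(p))
    mu <- expit_(beta[1] + beta[2] * grid + beta[3] * cohort$z[i])
    lik <- if (cohort$y[i] == 1) mu else 1 - mu
    if (cohort$v[i] == 1) {
      k <- which.min(abs(grid - cohort$x_validated[i]))
      ll <- ll + log(lik[k]) + log(q_i[k])
    } else ll <- ll + log(sum(lik * q_i))
  }
  ll
}

test_that("naive logistic fit recovers parameters without corruption", {
  cfg <- quick_config(n = 10000, seed = 19, tpr = 1, fpr = 0, missingness = 0)
  co <- generate_cohort(cfg)
  fit <- fit_naive(co)
  expect_true(all(abs(fit$beta - cfg$beta) < 2.5 * fit$se))
  # independence world: slopes near zero, intercept near logit of the rate
  set.seed(2); n <- 4000
  co0 <- make_cohort_df(y = rep(c(0, 1), n / 2), x_star = runif(n),
                        z = rnorm(n))
  f0 <- fit_naive(co0)
  expect_lt(abs(f0$beta[2]), 3 * f0$se[2])
  expect_lt(abs(f0$beta[1] - stats::qlogis(0.5)), 3 * f0$se[1])
})

test_that("naive fit reports separation instead of hiding it", {
  set.seed(3)
  x <- runif(60)
  co <- make_cohort_df(y = as.integer(x > 0.5), x_star = x, z = rnorm(60))
  expect_warning(fit_naive(co), "separation")
})

test_that("observed log-likelihood matches the enumeration oracle", {
  grid <- c(0, 0.5, 1)
  basis <- sieve_basis(c(0.2, 0.5, 0.8), degree = 1, n_basis = 2)
  p <- cbind(c(0.5, 0.3, 0.2), c(0.1, 0.3, 0.6))
  beta <- c(0.2, -0.5, 0.1)
  co <- make_cohort_df(y = c(1, 0, 1, 0), x_star = c(0.4, 0.1, 0.9, 0.6),
                       z = c(0.5, -1, 2, 0),
                       v = c(1L, 0L, 0L, 1L),
                       x_validated = c(1, NA, NA, 0.5))
  expect_equal(observed_loglik(beta, p, co, grid, basis),
               loglik_oracle(beta, p, co, grid, basis), tolerance = 1e-10)
})

test_that("degenerate error model collapses to the naive log-likelihood", {
  # identity p on a two-point support: unvalidated patients contribute
  # exactly the standard logistic likelihood at X = X*
  grid <- c(0, 1)
  basis <- sieve_basis(c(0, 1), degree = 0, n_basis = 2)
  basis$knots <- 0.5
  p <- diag(2)
  beta <- c(-0.3, 0.8, 0.2)
  co <- make_cohort_df(y = c(1, 0, 1), x_star = c(0, 1, 1), z = c(0.2, -0.4, 1))
  eta <- beta[1] + beta[2] * co$x_star + beta[3] * co$z
  naive_ll <- sum(co$y * log(expit_(eta)) + (1 - co$y) * log(1 - expit_(eta)))
  expect_equal(observed_loglik(beta, p, co, grid, basis), naive_ll,
               tolerance = 1e-10)
})

test_that("with everyone validated the SMLE equals the complete-data MLE", {
  cfg <- quick_config(n = 400, seed = 23, tpr = 0.9, fpr = 0.05,
                      missingness = 0.2, recovery_rate = 0.5)
  co <- generate_cohort(cfg)
  co <- apply_validation(co, co$id, cfg, seed = 2)
  # snap the validated exposure as the SMLE will see it
  co$x_validated <- ali_grid()[
    vapply(co$x_validated, function(v) which.min(abs(ali_grid() - v)), 1L)]
  fit <- fit_smle(co, tol = 1e-7, max_iter = 5000)
  ref <- stats::glm(y ~ x_validated + z, stats::binomial(), co)
  expect_equal(unname(fit$beta), unname(stats::coef(ref)), tolerance = 1e-4)
  # profile-likelihood SEs agree with the complete-data logistic SEs
  pr <- profile_se(fit, co)
  expect_true(pr$success)
  expect_equal(pr$se, unname(sqrt(diag(stats::vcov(ref)))), tolerance = 0.05)
})

test_that("EM matches brute-force maximization on tiny instances", {
  grid <- c(0, 0.5, 1)
  basis <- sieve_basis(0.5, degree = 0, n_basis = 1)   # constant basis
  brute <- function(co, extra_starts = list()) {
    obj <- function(theta) {
      p <- matrix(exp(c(theta[4:5], 0)), 3, 1)
      p <- p / sum(p)
      -observed_loglik(theta[1:3], p, co, grid, basis)
    }
    best <- NULL
    starts <- c(list(rep(0, 5), c(1, -1, 0.5, 0.5, -0.5), c(-1, 2, 0, 1, 1)),
                extra_starts)
    for (s in starts) {
      o <- stats::optim(s, obj, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
    best
  }
  # interior optimum: repeated covariate points with opposing outcomes
  co1 <- make_cohort_df(y = c(1, 0, 0, 1, 1),
                        x_star = c(0.5, 0.5, 0.3, 0.3, 0.8),
                        z = c(0, 0, 1, 1, 0.5),
                        v = c(1L, 1L, 1L, 1L, 0L),
                        x_validated = c(0.5, 0.5, 1, 1, NA))
  fit1 <- suppressWarnings(fit_smle(co1, grid = grid, basis = basis,
                                    tol = 1e-10, max_iter = 50000,
                                    start_beta = c(0, 0, 0)))
  best1 <- brute(co1)
  expect_equal(utils::tail(fit1$loglik_trace, 1), -best1$value,
               tolerance = 1e-6)
  expect_equal(unname(fit1$beta), best1$par[1:3], tolerance = 1e-3)
  p_opt <- exp(c(best1$par[4:5], 0)); p_opt <- p_opt / sum(p_opt)
  expect_equal(as.numeric(fit1$p), p_opt, tolerance = 1e-3)
  # a second instance whose maximum sits on a likelihood ridge: the EM
  # must still attain the brute-force maximum of the objective
  co2 <- make_cohort_df(y = c(0, 1, 1, 0, 0),
                        x_star = c(0.3, 0.7, 0.5, 0.6, 0.1),
                        z = c(0.5, 1, -1, 0, 2),
                        v = c(1L, 1L, 0L, 0L, 1L),
                        x_validated = c(0, 1, NA, NA, 0.5))
  fit2 <- suppressWarnings(fit_smle(co2, grid = grid, basis = basis,
                                    tol = 1e-10, max_iter = 50000,
                                    start_beta = c(0, 0, 0)))
  best2 <- brute(co2)
  expect_gte(utils::tail(fit2$loglik_trace, 1), -best2$value - 1e-4)
})

test_that("EM invariants: monotone log-likelihood, normalized error model", {
  for (s in c(101, 202, 303)) {
    cfg <- quick_config(n = 300, seed = s, tpr = 0.95, fpr = 0.05,
                        missingness = 0.15, recovery_rate = 0.8)
    co <- generate_cohort(cfg)
    d <- sample_srs(co, 60, seed = s)
    co <- apply_validation(co, d$selected_ids, cfg, seed = s + 1)
    fit <- fit_smle(co)
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
    expect_equal(unname(colSums(fit$p)), rep(1, ncol(fit$p)), tolerance = 1e-8)
    # sum_k Pr(x_k | X*) = 1 for every patient in the data
    q <- basis_matrix(fit$basis, co$x_star, co$z) %*% t(fit$p)
    expect_equal(unname(rowSums(q)), rep(1, nrow(co)), tolerance = 1e-8)
    expect_true(all(fit$p >= 0))
  }
})

test_that("profile SEs are stable in h and scale with n", {
  cfg <- quick_config(n = 400, seed = 55, tpr = 1, fpr = 0.02,
                      missingness = 0.1, recovery_rate = 0.9)
  co <- generate_cohort(cfg)
  d <- sample_srs(co, 80, seed = 5)
  co <- apply_validation(co, d$selected_ids, cfg, seed = 6)
  fit <- fit_smle(co)
  ses <- sapply(c(0.5, 1, 2), function(h) profile_se(fit, co, h_scale = h)$se)
  expect_true(all(abs(ses[, 1] / ses[, 2] - 1) < 0.01))
  expect_true(all(abs(ses[, 3] / ses[, 2] - 1) < 0.01))
  # quadrupling the cohort (and validation sample) shrinks the variance
  # roughly fourfold
  cfg2 <- cfg; cfg2$n_patients <- 1600L; cfg2$seed <- 56L
  co2 <- generate_cohort(cfg2)
  d2 <- sample_srs(co2, 320, seed = 5)
  co2 <- apply_validation(co2, d2$selected_ids, cfg2, seed = 6)
  fit2 <- fit_smle(co2)
  se2 <- profile_se(fit2, co2)$se
  ratio <- (ses[2, 2] / se2[2])^2        # ALI coefficient variance ratio
  expect_gt(ratio, 2); expect_lt(ratio, 8)
})

test_that("predicted validated ALI follows the posterior-mean formula", {
  # identity error model: prediction returns X* itself
  grid <- ali_grid()
  basis <- sieve_basis(grid, degree = 0, n_basis = 11)
  basis$knots <- seq(0.05, 0.95, 0.1)
  fit <- structure(list(beta = c(0, 1, 0), p = diag(11), grid = grid,
                        basis = basis), class = "ali_smle")
  nd <- make_cohort_df(y = c(1, 0), x_star = c(0.3, 0.7), z = c(0, 0))
  expect_equal(predict_validated_ali(fit, nd), c(0.3, 0.7))
  expect_equal(predict_validated_ali(fit, nd, use_outcome = FALSE), c(0.3, 0.7))
  # two-point support with hand-set probabilities: arithmetic oracle
  basis2 <- sieve_basis(0.5, degree = 0, n_basis = 1)
  fit2 <- structure(list(beta = c(-0.5, 1, 0), p = matrix(c(0.4, 0.6), 2, 1),
                         grid = c(0, 1), basis = basis2), class = "ali_smle")
  nd2 <- make_cohort_df(y = 1, x_star = 0.5, z = 0)
  w1 <- expit_(-0.5 + 0) * 0.4; w2 <- expit_(0.5) * 0.6
  expect_equal(predict_validated_ali(fit2, nd2), w2 / (w1 + w2))
  expect_equal(predict_validated_ali(fit2, nd2, use_outcome = FALSE), 0.6)
  # predictions are convex combinations of the grid
  cfg <- quick_config(n = 200, seed = 77)
  co <- generate_cohort(cfg)
  d <- sample_srs(co, 40, seed = 1)
  co <- apply_validation(co, d$selected_ids, cfg)
  f <- fit_smle(co)
  pr <- predict_validated_ali(f, co)
  expect_true(all(pr >= 0 & pr <= 1))
  # validated patients pass through unchanged
  expect_equal(pr[co$v == 1], co$x_validated[co$v == 1])
})

test_that("degenerate inputs fail loudly", {
  co <- make_cohort_df(y = c(1, 0), x_star = c(0.2, 0.4), z = c(0, 1))
  expect_error(fit_smle(co), "at least one validated")
  co$v[1] <- 1L
  expect_error(fit_smle(co), "x_validated")
})

test_that("reporting scale converts coefficients to odds quantities", {
  out <- utilization_odds_summary(c(log(0.25), 10 * log(1.1), log(1.11)),
                                  se = c(0.1, 0.2, 0.05))
  expect_equal(out$estimate, c(0.25, 1.1, 1.11), tolerance = 1e-12)
  expect_true(all(out$ci_lower < out$estimate & out$estimate < out$ci_upper))
})
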