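#' Support grid for validated ALI
#'
#' The validated ALI of a patient with all ten components non-missing takes
#' values in `{0, 0.1, ..., 1}`; this tenths grid is the default support of
#' the error mechanism `Pr(X = x | X*)`.
#'
#' @param by grid spacing.
#' @return numeric vector of support points in `[0, 1]`.
#' @export
ali_grid <- function(by = 0.1) seq(0, 1, by = by)

#' Construct the B-spline sieve basis for the error mechanism
#'
#' The nonparametric error mechanism `Pr(X = x_k | X*)` is approximated by
#' a sieve: `Pr(x_k | X*) = sum_j B_j(X*) p_kj` where the `B_j` are
#' B-spline basis functions of `X*` forming a partition of unity
#' (nonnegative, summing to 1 at any `X*`), and the columns `p_.j` are
#' probability vectors over the grid. Interior knots sit at empirical
#' quantiles of `X*`; the default dimension is `ceiling(3 * n_validated^(1/3))`.
#'
#' With `conditioning = "x_star_and_z"` the basis is additionally
#' stratified by tertile of `Z`, tripling its dimension — usable, but
#' subject to the curse of dimensionality for small validation samples.
#'
#' @param x_star error-prone ALI values used to place the knots.
#' @param n_validated number of validated patients (sets the default
#'   dimension).
#' @param n_basis number of basis functions of `X*`; overrides the default.
#' @param degree spline degree; the default is 1 (local linear sieve,
#'   deliberately undersmoothed: global cubic smoothing of a sharply
#'   varying error mechanism attenuates the exposure coefficient), 0 gives
#'   a histogram sieve.
#' @param conditioning `"x_star_only"` (default) or `"x_star_and_z"`.
#' @param z_breaks number of `Z` strata when conditioning on `Z`.
#' @return an object of class `sieve_basis`.
#' @export
sieve_basis <- function(x_star, n_validated = length(x_star), n_basis = NULL,
                        degree = 1, conditioning = c("x_star_only", "x_star_and_z"),
                        z_breaks = 3) {
  conditioning <- match.arg(conditioning)
  if (is.null(n_basis)) n_basis <- max(degree + 1, ceiling(3 * n_validated^(1 / 3)))
  n_interior <- max(0L, as.integer(n_basis) - as.integer(degree) - 1L)
  knots <- numeric(0)
  if (n_interior > 0L) {
    probs <- seq_len(n_interior) / (n_interior + 1)
    knots <- unique(stats::quantile(x_star, probs, names = FALSE, type = 7))
    knots <- knots[knots > 1e-9 & knots < 1 - 1e-9]
  }
  structure(list(degree = degree, knots = knots,
                 n_basis = degree + 1L + length(knots),
                 conditioning = conditioning, z_breaks = z_breaks,
                 z_quantiles = NULL),
            class = "sieve_basis")
}

#' Evaluate the sieve basis
#'
#' @param basis a [sieve_basis()].
#' @param x values of `X*` (clamped to `[0, 1]` with a warning).
#' @param z covariate values; required when the basis conditions on `Z`.
#' @return matrix with one row per element of `x`; rows sum to 1.
#' @export
basis_matrix <- function(basis, x, z = NULL) {
  if (any(x < 0 | x > 1)) {
    warning("x_star outside [0, 1]; clamped to the basis range")
    x <- pmin(pmax(x, 0), 1)
  }
  if (basis$degree == 0) {
    # histogram sieve: indicator of the bin between consecutive knots
    bin <- findInterval(x, basis$knots) + 1L
    B <- matrix(0, length(x), length(basis$knots) + 1L)
    B[cbind(seq_along(x), bin)] <- 1
  } else {
    B <- splines::bs(x, knots = basis$knots, degree = basis$degree,
                     intercept = TRUE, Boundary.knots = c(0, 1))
    B <- unclass(B); attributes(B)[c("knots", "degree", "intercept",
                                     "Boundary.knots")] <- NULL
  }
  if (basis$conditioning == "x_star_and_z") {
    if (is.null(z)) stop("z is required when the basis conditions on Z")
    qs <- basis$z_quantiles
    if (is.null(qs))
      qs <- stats::quantile(z, seq_len(basis$z_breaks - 1) / basis$z_breaks,
                            names = FALSE)
    g <- findInterval(z, qs) + 1L
    out <- matrix(0, length(x), ncol(B) * basis$z_breaks)
    for (s in seq_len(basis$z_breaks)) {
      rows <- g == s
      out[rows, (s - 1L) * ncol(B) + seq_len(ncol(B))] <- B[rows, , drop = FALSE]
    }
    return(out)
  }
  B
}

#' Fit the naive logistic healthcare-utilization model
#'
#' Standard logistic regression of the outcome on an error-prone exposure
#' (`x_star` by default) and the age covariate `z`, ignoring measurement
#' error and missingness. Used as a baseline, to initialize the sieve MLE,
#' and to compute residuals for residual sampling.
#'
#' @param cohort data frame with columns `y`, `z`, and the exposure.
#' @param exposure exposure column name.
#' @return list of class `ali_naive_fit` with `beta`, `se`, `ci`, `vcov`,
#'   `loglik`, `converged`. Quasi-separation is reported with a warning,
#'   never silently regularized.
#' @export
fit_naive <- function(cohort, exposure = "x_star") {
  df <- data.frame(y = cohort$y, x = cohort[[exposure]], z = cohort$z)
  if (anyNA(df)) stop("y, ", exposure, ", z must be complete")
  fit <- suppressWarnings(stats::glm(y ~ x + z, family = stats::binomial(), data = df))
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 15)
  if (sep) warning("possible separation in the naive logistic fit; ",
                   "coefficients may be unstable")
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(stats::vcov(fit))))
  structure(list(beta = beta, se = se,
                 ci = cbind(lower = beta - 1.96 * se, upper = beta + 1.96 * se),
                 vcov = stats::vcov(fit), loglik = as.numeric(stats::logLik(fit)),
                 converged = fit$converged, separation = sep,
                 n = nrow(df), exposure = exposure),
            class = "ali_naive_fit")
}

snap_to_grid <- function(x, grid)
  vapply(x, function(v) which.min(abs(grid - v)), integer(1))

expit <- function(x) 1 / (1 + exp(-x))

# Bernoulli likelihood matrix L[i, k] = Pr_beta(Y_i | x_k, Z_i)
outcome_lik_matrix <- function(beta, y, z, grid) {
  mu <- expit(outer(beta[1] + beta[3] * z, beta[2] * grid, `+`))
  y * mu + (1 - y) * (1 - mu)          # y recycles down columns
}

#' Observed-data log-likelihood of the partially validated cohort
#'
#' Validated patients contribute `log Pr_beta(Y | X, Z) + log Pr(X | X*, Z)`;
#' unvalidated patients contribute the log of the mixture
#' `sum_k Pr_beta(Y | x_k, Z) Pr(x_k | X*, Z)`. The validation-sampling
#' probability is omitted (validated ALI is missing at random because every
#' design conditions only on fully observed data) and the marginal of
#' `(X*, Z)` drops out of the maximization over `beta`.
#'
#' @param beta length-3 log-odds coefficients.
#' @param p `K x J` matrix of sieve coefficients; column `j` is a
#'   probability vector over the grid.
#' @param cohort an `ali_cohort` (or data frame with `y`, `z`, `x_star`,
#'   `v`, `x_validated`).
#' @param grid support points of validated ALI.
#' @param basis a [sieve_basis()].
#' @param floor lower bound applied inside logarithms (numerical guard).
#' @return scalar log-likelihood. A mixture probability of exactly zero for
#'   an unvalidated patient signals a support/basis misconfiguration and is
#'   an error.
#' @export
observed_loglik <- function(beta, p, cohort, grid, basis, floor = 1e-12) {
  B <- basis_matrix(basis, cohort$x_star, cohort$z)
  q <- B %*% t(p)                               # N x K: Pr(x_k | X*_i)
  L <- outcome_lik_matrix(beta, cohort$y, cohort$z, grid)
  val <- cohort$v == 1L
  ll <- 0
  if (any(val)) {
    ki <- snap_to_grid(cohort$x_validated[val], grid)
    iv <- which(val)
    ll <- ll + sum(log(pmax(L[cbind(iv, ki)], floor))) +
      sum(log(pmax(q[cbind(iv, ki)], floor)))
  }
  if (any(!val)) {
    mix <- rowSums((L * q)[!val, , drop = FALSE])
    if (any(mix == 0))
      stop("zero mixture probability for an unvalidated patient: ",
           "the support grid/basis does not cover the data")
    ll <- ll + sum(log(pmax(mix, floor)))
  }
  ll
}

# weighted logistic M-step by IRLS with step-halving; ensures the weighted
# complete-data log-likelihood never decreases (generalized EM)
weighted_logistic_step <- function(E, yy, w, beta, max_iter = 2, tol = 1e-10) {
  Q <- function(mu)
    sum(w * (yy * log(pmax(mu, 1e-300)) + (1 - yy) * log(pmax(1 - mu, 1e-300))))
  mu <- expit(drop(E %*% beta))
  q0 <- Q(mu)
  for (it in seq_len(max_iter)) {
    ww <- w * mu * (1 - mu)
    g <- crossprod(E, w * (yy - mu))
    H <- crossprod(E * ww, E)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    newb <- beta + step
    mun <- expit(drop(E %*% newb))
    qn <- Q(mun)
    halves <- 0
    while (qn < q0 && halves < 20) {
      step <- step / 2; newb <- beta + step
      mun <- expit(drop(E %*% newb)); qn <- Q(mun); halves <- halves + 1
    }
    if (qn < q0) break                 # no uphill step found: keep beta
    moved <- max(abs(newb - beta))
    beta <- drop(newb); mu <- mun; q0 <- qn
    if (moved < tol) break
  }
  beta
}

#' Sieve maximum likelihood estimation for partially validated ALI data
#'
#' Maximizes the observed-data log-likelihood over the logistic coefficients
#' `beta` and the sieve error mechanism `Pr(X = x_k | X*)` by EM. The
#' E-step computes, for each unvalidated patient, posterior weights over the
#' grid `w_ik ∝ Pr_beta(Y_i | x_k, Z_i) Pr(x_k | X*_i, Z_i)` (validated
#' patients carry point mass at their observed validated ALI). The M-step
#' updates `beta` by weighted logistic regression over the patient-by-grid
#' expansion and updates the sieve coefficients in closed form,
#' `p_kj = sum_i B_ij w_ik / sum_i B_ij`, which keeps every column a
#' probability vector.
#'
#' @param cohort an `ali_cohort` with at least one validated patient.
#' @param grid support of validated ALI; ignored when
#'   `support = "observed"`, which uses the observed validated values.
#' @param basis optional [sieve_basis()]; built from the cohort by default.
#' @param conditioning,n_basis,degree passed to [sieve_basis()] when
#'   `basis` is `NULL`.
#' @param support `"tenths"` snaps validated ALI to `grid` (its default is
#'   the tenths grid); `"observed"` uses the exact observed support.
#' @param tol EM stops when the largest absolute change across `beta` and
#'   `p` falls below this.
#' @param max_iter EM iteration cap; hitting it flags non-convergence.
#' @param se compute profile-likelihood standard errors via [profile_se()].
#' @param start_beta optional starting coefficients (default: naive fit).
#' @return an object of class `ali_smle`: `beta`, `p`, `grid`, `basis`,
#'   `loglik_trace` (nondecreasing), `converged`, `n_iter`, `naive`, and —
#'   when `se = TRUE` — `se`, `ci`, `vcov`.
#' @export
fit_smle <- function(cohort, grid = ali_grid(), basis = NULL,
                     conditioning = "x_star_only", n_basis = NULL, degree = 1,
                     support = c("tenths", "observed"),
                     tol = 1e-4, max_iter = 1000, se = FALSE,
                     start_beta = NULL) {
  support <- match.arg(support)
  val <- cohort$v == 1L
  if (!any(val)) stop("at least one validated patient is required")
  if (anyNA(cohort$x_validated[val]))
    stop("validated patients must have x_validated")
  if (support == "observed") grid <- sort(unique(cohort$x_validated[val]))
  K <- length(grid)
  n_val <- sum(val)
  if (is.null(basis))
    basis <- sieve_basis(cohort$x_star, n_validated = n_val,
                         n_basis = n_basis, degree = degree,
                         conditioning = conditioning)
  B <- basis_matrix(basis, cohort$x_star, cohort$z)
  J <- ncol(B)
  if (any(colSums(B) < 1e-8))
    warning("empty sieve basis cell(s): some basis functions receive no ",
            "data; their coefficients stay at their initial value")
  N <- nrow(cohort)
  ki <- snap_to_grid(cohort$x_validated[val], grid)
  naive <- fit_naive(cohort)
  beta <- if (is.null(start_beta)) naive$beta else start_beta

  # p init: validated empirical frequencies smoothed toward uniform
  f <- tabulate(ki, nbins = K) / n_val
  p <- matrix(0.9 * f + 0.1 / K, K, J)
  p <- sweep(p, 2, colSums(p), `/`)

  # fixed patient-by-grid expansion for the weighted logistic M-step
  E <- cbind(1, rep(grid, each = N), rep(cohort$z, K))
  yy <- rep(cohort$y, K)
  iv <- which(val); iu <- which(!val)
  psi <- matrix(0, N, K)
  psi[cbind(iv, ki)] <- 1

  # one EM map application: E-step at (beta, p), then joint M-step
  # (Q separates in beta and p); also returns the observed log-likelihood
  # at the *input* parameters
  em_step <- function(beta, p) {
    L <- outcome_lik_matrix(beta, cohort$y, cohort$z, grid)
    q <- B %*% t(p)
    mix <- NULL
    if (length(iu)) {
      w <- (L * q)[iu, , drop = FALSE]
      mix <- rowSums(w)
      if (any(mix == 0))
        stop("zero mixture probability for an unvalidated patient: ",
             "the support grid/basis does not cover the data")
      psi[iu, ] <<- w / mix
    }
    ll <- sum(log(pmax(L[cbind(iv, ki)], 1e-12))) +
      sum(log(pmax(q[cbind(iv, ki)], 1e-12))) +
      (if (length(iu)) sum(log(pmax(mix, 1e-12))) else 0)
    # sieve update with the basis index treated as latent alongside X:
    # phi_ikj = psi_ik B_ij p_kj / q_ik, p_kj <- sum_i phi / colsum(phi)
    p_new <- p * crossprod(psi / pmax(q, 1e-300), B)
    cs <- colSums(p_new)
    zero_cols <- cs < 1e-12                     # vanishing basis cell
    for (j in which(zero_cols)) {
      p_new[, j] <- p[, j]
      cs[j] <- 1
    }
    p_new <- sweep(p_new, 2, cs, `/`)
    beta_new <- weighted_logistic_step(E, yy, as.vector(psi), beta)
    list(beta = beta_new, p = p_new, ll = ll)
  }
  obj <- function(beta, p) {
    L <- outcome_lik_matrix(beta, cohort$y, cohort$z, grid)
    q <- B %*% t(p)
    sum(log(pmax(L[cbind(iv, ki)], 1e-12))) +
      sum(log(pmax(q[cbind(iv, ki)], 1e-12))) +
      (if (length(iu))
        sum(log(pmax(rowSums((L * q)[iu, , drop = FALSE]), 1e-12))) else 0)
  }
  fix_p <- function(pv) {
    pm <- matrix(pmax(pv, 1e-12), K, J)
    sweep(pm, 2, colSums(pm), `/`)
  }

  trace <- numeric(0)
  converged <- FALSE
  n_map <- 0L
  # SQUAREM-accelerated EM with a monotonicity safeguard: extrapolated
  # steps are only accepted when they do not decrease the log-likelihood;
  # otherwise the plain EM step is used. Convergence is judged on the
  # residual of the plain EM map, max |F(theta) - theta| < tol.
  while (n_map < max_iter) {
    s1 <- em_step(beta, p); n_map <- n_map + 1L
    trace <- c(trace, s1$ll)
    if (max(max(abs(s1$beta - beta)), max(abs(s1$p - p))) < tol) {
      beta <- s1$beta; p <- s1$p; converged <- TRUE; break
    }
    s2 <- em_step(s1$beta, s1$p); n_map <- n_map + 1L
    trace <- c(trace, s2$ll)
    t0 <- c(beta, as.vector(p)); t1 <- c(s1$beta, as.vector(s1$p))
    t2 <- c(s2$beta, as.vector(s2$p))
    r <- t1 - t0; v <- (t2 - t1) - r
    vv <- sum(v * v)
    accepted <- FALSE
    if (vv > 1e-300) {
      alpha <- min(-1, -sqrt(sum(r * r) / vv))
      te <- t0 - 2 * alpha * r + alpha^2 * v
      be <- te[1:3]; pe <- fix_p(te[-(1:3)])
      if (all(is.finite(be)) && obj(be, pe) >= s2$ll) {
        beta <- be; p <- pe; accepted <- TRUE
      }
    }
    if (!accepted) { beta <- s2$beta; p <- s2$p }
  }
  fit <- structure(list(
    beta = stats::setNames(beta, c("(Intercept)", "ali", "age_decade")),
    p = p, grid = grid, basis = basis, loglik_trace = trace,
    converged = converged, n_iter = length(trace), naive = naive,
    n = N, n_validated = n_val, support = support,
    se = NULL, ci = NULL, vcov = NULL), class = "ali_smle")
  if (se) {
    pr <- profile_se(fit, cohort)
    fit$se <- pr$se; fit$ci <- pr$ci; fit$vcov <- pr$vcov
  }
  fit
}

#' @export
print.ali_smle <- function(x, ...) {
  cat("Sieve MLE logistic fit (N =", x$n, ", validated =", x$n_validated, ")\n")
  cat(if (x$converged) "Converged" else "DID NOT CONVERGE",
      "after", x$n_iter, "EM iterations\n")
  tab <- data.frame(estimate = unname(x$beta))
  rownames(tab) <- names(x$beta)
  if (!is.null(x$se)) {
    tab$se <- x$se
    tab$ci_lower <- x$ci[, 1]; tab$ci_upper <- x$ci[, 2]
  }
  print(tab)
  invisible(x)
}

# maximize the sieve coefficients p at fixed beta (E + p steps only)
profile_p <- function(beta, cohort, grid, basis, p0, tol = 1e-8,
                      max_iter = 500) {
  B <- basis_matrix(basis, cohort$x_star, cohort$z)
  val <- cohort$v == 1L
  iv <- which(val); iu <- which(!val)
  ki <- snap_to_grid(cohort$x_validated[val], grid)
  N <- nrow(cohort); K <- length(grid)
  psi <- matrix(0, N, K)
  psi[cbind(iv, ki)] <- 1
  L <- outcome_lik_matrix(beta, cohort$y, cohort$z, grid)
  p <- p0
  for (it in seq_len(max_iter)) {
    q <- B %*% t(p)
    if (length(iu)) {
      w <- (L * q)[iu, , drop = FALSE]
      psi[iu, ] <- w / pmax(rowSums(w), 1e-300)
    }
    p_new <- p * crossprod(psi / pmax(q, 1e-300), B)
    cs <- colSums(p_new)
    keep <- cs >= 1e-12
    p_new[, !keep] <- p[, !keep]
    cs[!keep] <- 1
    p_new <- sweep(p_new, 2, cs, `/`)
    if (max(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  observed_loglik(beta, p, cohort, grid, basis)
}

#' Profile-likelihood standard errors for the sieve MLE
#'
#' The information matrix for `beta` is estimated by numerically
#' differentiating the profile log-likelihood `pl(beta) = max_p loglik`
#' (the sieve coefficients are re-maximized at each perturbed `beta`):
#' `I[j,k] = -(pl(b + h_j e_j + h_k e_k) - pl(b + h_j e_j) -
#' pl(b + h_k e_k) + pl(b)) / (h_j h_k)`. Steps are set in two passes: a
#' pilot pass with `1/sqrt(N)` steps yields provisional SEs, and the
#' reported pass uses `h_j = h_scale * se_j`, so each coefficient is
#' perturbed on its own uncertainty scale. 95% confidence intervals are
#' `estimate ± 1.96 SE`.
#'
#' @param fit a converged [fit_smle()] result.
#' @param cohort the cohort the fit was computed on.
#' @param h_scale multiplier on the per-coefficient step.
#' @return list with `se`, `ci`, `vcov`, `h`, `success`. Non-positive
#'   curvature is reported (`success = FALSE`, `NA` SEs) rather than
#'   silently fixed.
#' @export
profile_se <- function(fit, cohort, h_scale = 1) {
  if (!fit$converged) warning("profiling a non-converged fit")
  b0 <- unname(fit$beta)
  d <- length(b0)
  pl <- function(b) profile_p(b, cohort, fit$grid, fit$basis, fit$p)
  pl0 <- pl(b0)
  # forward second differences: cheap, used for the pilot step sizes
  curvature_fwd <- function(h) {
    pl_j <- vapply(seq_len(d), function(j) {
      b <- b0; b[j] <- b[j] + h[j]; pl(b)
    }, numeric(1))
    I <- matrix(NA_real_, d, d)
    for (j in seq_len(d)) for (k in j:d) {
      b <- b0; b[j] <- b[j] + h[j]; b[k] <- b[k] + h[k]
      I[j, k] <- I[k, j] <- -(pl(b) - pl_j[j] - pl_j[k] + pl0) / (h[j] * h[k])
    }
    I
  }
  # central second differences: O(h^2) accurate, used for the report
  curvature <- function(h) {
    at <- function(s) {
      b <- b0 + s * h
      pl(b)
    }
    I <- matrix(NA_real_, d, d)
    for (j in seq_len(d)) {
      s <- rep(0, d)
      s[j] <- 1; up <- at(s)
      s[j] <- -1; dn <- at(s)
      I[j, j] <- -(up - 2 * pl0 + dn) / h[j]^2
    }
    for (j in seq_len(d)) for (k in seq_len(d)) {
      if (k <= j) next
      s <- rep(0, d)
      s[j] <- 1; s[k] <- 1; pp <- at(s)
      s[k] <- -1; pm <- at(s)
      s[j] <- -1; s[k] <- 1; mp <- at(s)
      s[k] <- -1; mm <- at(s)
      I[j, k] <- I[k, j] <- -(pp - pm - mp + mm) / (4 * h[j] * h[k])
    }
    I
  }
  fail <- function(h) {
    warning("profile information matrix is not positive definite; ",
            "no standard errors reported")
    list(se = rep(NA_real_, d), ci = matrix(NA_real_, d, 2),
         vcov = NULL, h = h, success = FALSE)
  }
  h_pilot <- rep(1 / sqrt(nrow(cohort)), d)
  I1 <- curvature_fwd(h_pilot)
  if (any(eigen(I1, symmetric = TRUE, only.values = TRUE)$values <= 0))
    return(fail(h_pilot))
  se_pilot <- sqrt(diag(solve(I1)))
  # 0.1 SE steps: small enough that the O(h^2) truncation error of the
  # central differences is negligible (the profile log-likelihood is
  # noticeably non-quadratic beyond ~0.3 SE at small validation samples),
  # large enough to dominate inner-EM noise in the profile evaluations
  h <- 0.1 * h_scale * se_pilot
  I2 <- curvature(h)
  if (any(eigen(I2, symmetric = TRUE, only.values = TRUE)$values <= 0))
    return(fail(h))
  V <- solve(I2)
  se <- sqrt(diag(V))
  list(se = se, ci = cbind(lower = b0 - 1.96 * se, upper = b0 + 1.96 * se),
       vcov = V, h = h, success = TRUE)
}

#' Predict validated ALI from the estimated error mechanism
#'
#' For unvalidated patients, the expected validated ALI given their
#' EHR data: with `use_outcome = TRUE` (default) the posterior mean
#' `sum_k x_k Pr_beta(Y|x_k,Z) Pr(x_k|X*,Z) / sum_k Pr_beta(Y|x_k,Z)
#' Pr(x_k|X*,Z)`, which uses all information in `(Y, X*, Z)`; with
#' `use_outcome = FALSE`, the error-mechanism mean `sum_k x_k Pr(x_k|X*,Z)`.
#' Validated patients return their observed validated ALI unchanged.
#'
#' @param fit an [fit_smle()] result.
#' @param newdata data frame with `x_star`, `z` (and `y` when
#'   `use_outcome`); a `v`/`x_validated` pair is honoured when present.
#' @param use_outcome condition the prediction on the observed outcome.
#' @return numeric vector of predictions, each within the grid range.
#' @export
predict_validated_ali <- function(fit, newdata, use_outcome = TRUE) {
  B <- basis_matrix(fit$basis, newdata$x_star, newdata$z)
  q <- B %*% t(fit$p)
  if (use_outcome) {
    if (is.null(newdata$y)) stop("use_outcome = TRUE requires a y column")
    L <- outcome_lik_matrix(unname(fit$beta), newdata$y, newdata$z, fit$grid)
    w <- L * q
  } else w <- q
  pred <- drop(w %*% fit$grid) / rowSums(w)
  if (!is.null(newdata$v)) {
    keep <- newdata$v == 1L & !is.na(newdata$x_validated)
    pred[keep] <- newdata$x_validated[keep]
  }
  pred
}

#' Present logistic coefficients on the reporting scale
#'
#' Converts `(b0, b1, b2)` — with the exposure on the ALI proportion scale
#' and age per decade — into the quantities reported in practice: baseline
#' odds for an 18-year-old with ALI 0 (`exp(b0)`), odds ratio per 0.1-point
#' (one-component) ALI increase (`exp(0.1 b1)`), and odds ratio per decade
#' of age (`exp(b2)`).
#'
#' @param beta length-3 coefficients.
#' @param se optional length-3 standard errors for 95% CIs.
#' @return data frame with `quantity`, `estimate`, and (with `se`)
#'   `ci_lower`, `ci_upper`.
#' @export
utilization_odds_summary <- function(beta, se = NULL) {
  stopifnot(length(beta) == 3)
  mult <- c(1, 0.1, 1)
  est <- exp(mult * beta)
  out <- data.frame(
    quantity = c("baseline_odds", "or_per_0.1_ali", "or_per_decade"),
    estimate = est)
  if (!is.null(se)) {
    out$ci_lower <- exp(mult * (beta - 1.96 * se))
    out$ci_upper <- exp(mult * (beta + 1.96 * se))
  }
  out
}
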