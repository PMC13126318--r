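test_that("SRS selects uniformly, deterministically given a seed", {
  co <- generate_cohort(quick_config(n = 40, seed = 2))
  d1 <- sample_srs(co, 10, seed = 5)
  d2 <- sample_srs(co, 10, seed = 5)
  expect_identical(d1$selected_ids, d2$selected_ids)
  expect_length(unique(d1$selected_ids), 10)
  expect_identical(sort(sample_srs(co, 40, seed = 1)$selected_ids), co$id)
  expect_error(sample_srs(co, 41), "exceeds")
  # selection frequency ~ n/N over repetitions
  freq <- rowMeans(vapply(1:2000, function(s)
    co$id %in% sample_srs(co, 10, seed = s)$selected_ids, logical(40)))
  expect_true(all(abs(freq - 0.25) < 0.04))
})

test_that("stratified designs honour their allocations", {
  # balanced cohort: 100 per (Y, X*_D) cell
  co <- make_cohort_df(y = rep(c(0, 1), each = 200),
                       x_star = rep(c(0.2, 0.6, 0.2, 0.6), each = 100),
                       z = rep(1:4, 100))
  d <- sample_bcc(co, 100, cutpoint = 0.4, seed = 1)
  expect_equal(unname(d$per_stratum_counts), rep(25L, 4))
  d52 <- sample_bcc(co, 52, cutpoint = 0.4, seed = 2)
  expect_equal(unname(d52$per_stratum_counts), rep(13L, 4))
  dcc <- sample_cc(co, 50, seed = 3)
  expect_equal(unname(dcc$per_stratum_counts), c(25L, 25L))
  expect_equal(as.integer(table(co$y[co$id %in% dcc$selected_ids])),
               c(25L, 25L))
})

test_that("stratum shortfall is redistributed to strata with room", {
  co <- make_cohort_df(y = c(rep(0, 5), rep(1, 95)),
                       x_star = runif(100), z = rnorm(100))
  d <- sample_cc(co, 60, seed = 4)   # wants 30/30 but only 5 controls exist
  expect_equal(sum(d$per_stratum_counts), 60L)
  expect_equal(unname(d$per_stratum_counts["Y=0"]), 5L)
  expect_equal(unname(d$per_stratum_counts["Y=1"]), 55L)
})

test_that("single-stratum stratified sampling reduces to SRS", {
  co <- make_cohort_df(y = rep(1, 30), x_star = runif(30), z = rnorm(30))
  d <- sample_stratified(co, factor(rep("all", 30)), 10, seed = 9)
  expect_length(d$selected_ids, 10)
  expect_true(all(d$selected_ids %in% co$id))
})

test_that("residuals match the printed-formula arithmetic", {
  beta <- c(-1.383, 0.945, 0.103)
  co <- make_cohort_df(y = c(1, 0, 1), x_star = c(0, 0, 0.33),
                       z = c(0, 0, 2))
  r <- compute_residuals(co, beta)
  # independent arithmetic oracle: r = y - 1/(1 + exp(-eta))
  expect_equal(r[1], 1 - 1 / (1 + exp(1.383)), tolerance = 1e-10)
  expect_equal(r[1], 0.7995, tolerance = 5e-4)
  expect_equal(r[2], -(1 / (1 + exp(1.383))), tolerance = 1e-10)
  eta3 <- -1.383 + 0.945 * 0.33 + 0.103 * 2
  expect_equal(r[3], 1 - 1 / (1 + exp(-eta3)), tolerance = 1e-10)
  expect_error(compute_residuals(make_cohort_df(1, NA, 0), beta), "non-missing")
})

test_that("residual sampling takes the two extreme tails", {
  set.seed(8)
  co <- make_cohort_df(y = rbinom(200, 1, 0.4), x_star = runif(200),
                       z = rnorm(200))
  beta <- c(-0.5, 1, 0.1)
  d <- sample_rs(co, 48, beta, seed = 1)
  expect_length(d$selected_ids, 48)
  r <- compute_residuals(co, beta)
  ord <- order(r)
  expect_setequal(d$selected_ids,
                  co$id[c(ord[1:24], rev(ord)[1:24])])
  # n = 2 picks exactly the argmin and argmax
  d2 <- sample_rs(co, 2, beta)
  expect_setequal(d2$selected_ids, co$id[c(which.min(r), which.max(r))])
})

test_that("ties at the selection boundary resolve by seed, count exact", {
  co <- make_cohort_df(y = rep(0, 12), x_star = rep(c(0.1, 0.5), each = 6),
                       z = rep(0, 12))
  # residuals tie within each x_star group
  d <- sample_rs(co, 6, c(0, 1, 0), seed = 3)
  expect_length(d$selected_ids, 6)
  expect_length(unique(d$selected_ids), 6)
  expect_identical(d$selected_ids, sample_rs(co, 6, c(0, 1, 0), seed = 3)$selected_ids)
  # low tail comes from the high-x_star group (more negative residual = 0 - p)
  r <- compute_residuals(co, c(0, 1, 0))
  low_ids <- co$id[r == min(r)]
  expect_equal(sum(d$selected_ids %in% low_ids), 3)
})

test_that("extreme tail sampling ranks a fully observed column only", {
  co <- make_cohort_df(y = rbinom(50, 1, 0.3), x_star = seq(0, 1, length = 50),
                       z = rnorm(50))
  d <- sample_ets(co, 10, seed = 2)
  xs <- sort(co$x_star)
  expect_setequal(co$x_star[co$id %in% d$selected_ids],
                  c(xs[1:5], rev(xs)[1:5]))
  expect_error(sample_ets(co, 10, rank_value = "x_true"), "MAR")
})

test_that("selection never depends on the true ALI", {
  # MAR by construction: permuting x_true leaves every selection unchanged
  co <- generate_cohort(quick_config(n = 120, seed = 6))
  co2 <- co
  co2$x_true <- sample(co2$x_true)
  beta <- fit_naive(co)$beta
  expect_identical(sample_srs(co, 20, seed = 1)$selected_ids,
                   sample_srs(co2, 20, seed = 1)$selected_ids)
  expect_identical(sample_bcc(co, 20, seed = 1)$selected_ids,
                   sample_bcc(co2, 20, seed = 1)$selected_ids)
  expect_identical(sample_rs(co, 20, beta, seed = 1)$selected_ids,
                   sample_rs(co2, 20, beta, seed = 1)$selected_ids)
  expect_identical(sample_ets(co, 20, seed = 1)$selected_ids,
                   sample_ets(co2, 20, seed = 1)$selected_ids)
})

test_that("multi-wave orchestration never reselects and tracks pools", {
  co <- generate_cohort(quick_config(n = 1000, seed = 10))
  waves <- run_multiwave(co, list(
    list(strategy = "bcc", n = 4, seed = 1, label = "pilot"),
    list(strategy = "bcc", n = 48, seed = 2, label = "waveI"),
    list(strategy = "rs", n = 48, seed = 3, label = "waveII")))
  ids <- unlist(lapply(waves, `[[`, "selected_ids"))
  expect_length(ids, 100)
  expect_length(unique(ids), 100)
  expect_equal(vapply(waves, `[[`, "", "wave_label"),
               c("pilot", "waveI", "waveII"))
  # zero-size wave leaves the pool unchanged
  w0 <- run_multiwave(co, list(list(strategy = "srs", n = 0, seed = 1),
                               list(strategy = "srs", n = 5, seed = 2)))
  expect_length(w0[[1]]$selected_ids, 0)
  expect_length(w0[[2]]$selected_ids, 5)
})

test_that("two SRS waves match one combined SRS in inclusion probability", {
  co <- generate_cohort(quick_config(n = 30, seed = 12))
  reps <- 1500
  f2 <- rowMeans(vapply(seq_len(reps), function(s) {
    w <- run_multiwave(co, list(list(strategy = "srs", n = 5, seed = s),
                                list(strategy = "srs", n = 5, seed = s + reps)))
    co$id %in% unlist(lapply(w, `[[`, "selected_ids"))
  }, logical(30)))
  # both schemes give inclusion probability 10/30
  expect_true(all(abs(f2 - 1 / 3) < 0.05))
})
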