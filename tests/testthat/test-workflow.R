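test_that("end-to-end workflow produces a complete, reproducible artifact set", {
  out1 <- file.path(tempdir(), "wf1"); out2 <- file.path(tempdir(), "wf2")
  cfg <- list(out_dir = out1, seed = 3,
              generator = list(n_patients = 300, missingness = 0.1,
                               recovery_rate = 0.9),
              waves = list(list(strategy = "bcc", n = 4, label = "pilot"),
                           list(strategy = "bcc", n = 24, label = "waveI"),
                           list(strategy = "rs", n = 24, label = "waveII")))
  res <- suppressWarnings(run_workflow(cfg))
  for (f in c("cohort.tsv", "cohort_validated.tsv", "waves.json",
              "fit_naive.json", "fit_final.json", "report.json",
              "manifest.json"))
    expect_true(file.exists(file.path(out1, f)))
  expect_equal(sum(res$cohort$v), 52)
  report <- jsonlite::read_json(file.path(out1, "report.json"),
                                simplifyVector = TRUE)
  expect_setequal(report$report$quantity,
                  c("baseline_odds", "or_per_0.1_ali", "or_per_decade"))
  expect_true(all(report$report$estimate > 0))
  # same config, fresh run: bit-identical artifacts
  cfg$out_dir <- out2
  suppressWarnings(run_workflow(cfg))
  for (f in c("cohort.tsv", "waves.json", "report.json"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  # wave selections are disjoint and recorded
  waves <- jsonlite::read_json(file.path(out1, "waves.json"),
                               simplifyVector = FALSE)
  ids <- unlist(lapply(waves, `[[`, "selected_ids"))
  expect_length(unique(ids), 52)
})

test_that("zero-wave config yields a naive-only run", {
  out <- file.path(tempdir(), "wf0")
  res <- run_workflow(list(out_dir = out, seed = 5,
                           generator = list(n_patients = 200),
                           waves = list()))
  expect_null(res$final)
  expect_true(file.exists(file.path(out, "fit_naive.json")))
  expect_false(file.exists(file.path(out, "fit_final.json")))
})

test_that("cohort and fit files round-trip through text formats", {
  cfg <- quick_config(n = 120, seed = 8, missingness = 0.1)
  co <- generate_cohort(cfg)
  d <- sample_srs(co, 30, seed = 1)
  co <- apply_validation(co, d$selected_ids, cfg)
  path <- tempfile(fileext = ".tsv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_equal(co2$x_star, co$x_star, tolerance = 1e-12)
  expect_identical(co2$v, co$v)
  fit <- fit_smle(co)
  fpath <- tempfile(fileext = ".json")
  write_smle(fit, fpath)
  fit2 <- read_smle(fpath)
  expect_equal(unname(fit2$beta), unname(fit$beta), tolerance = 1e-12)
  expect_equal(fit2$p, fit$p, tolerance = 1e-12, ignore_attr = TRUE)
  # predictions from the file match predictions from the fit
  expect_equal(predict_validated_ali(fit2, co), predict_validated_ali(fit, co),
               tolerance = 1e-10)
})

test_that("the CLI wires subcommands to the workflow stages", {
  td <- file.path(tempdir(), "cli")
  dir.create(td, showWarnings = FALSE)
  cohort_file <- file.path(td, "cohort.tsv")
  gen_cfg <- file.path(td, "gen.json")
  jsonlite::write_json(list(n_patients = 150, missingness = 0.1,
                            recovery_rate = 0.9, seed = 4),
                       gen_cfg, auto_unbox = TRUE)
  ali_cli(c("generate", "--config", gen_cfg, "--out", cohort_file))
  expect_true(file.exists(cohort_file))
  co <- read_cohort(cohort_file)
  expect_equal(nrow(co), 150)

  design_file <- file.path(td, "design.json")
  ali_cli(c("design", "--cohort", cohort_file, "--strategy", "rs",
            "--n", "20", "--seed", "2", "--out", design_file))
  sel <- jsonlite::read_json(design_file, simplifyVector = TRUE)
  expect_length(sel$selected_ids, 20)

  validated_file <- file.path(td, "cohort_val.tsv")
  ali_cli(c("validate", "--cohort", cohort_file, "--ids", design_file,
            "--config", gen_cfg, "--seed", "3", "--out", validated_file))
  fit_file <- file.path(td, "fit.json")
  ali_cli(c("fit", "--cohort", validated_file, "--out", fit_file))
  expect_true(file.exists(fit_file))

  pred_file <- file.path(td, "pred.tsv")
  ali_cli(c("predict", "--fit", fit_file, "--cohort", validated_file,
            "--out", pred_file))
  pred <- utils::read.delim(pred_file)
  expect_equal(nrow(pred), 150)
  expect_true(all(pred$predicted_validated_ali >= 0 &
                    pred$predicted_validated_ali <= 1))
  expect_error(ali_cli("nonsense"), "unknown subcommand")
  expect_error(ali_cli(c("fit", "--se")), "missing required option --cohort")
})

test_that("the simulate subcommand writes a summary and a recommendation", {
  td <- file.path(tempdir(), "cli-sim")
  dir.create(td, showWarnings = FALSE)
  cfg <- file.path(td, "sim.json")
  jsonlite::write_json(list(
    generator = list(n_patients = 200, missingness = 0.1,
                     recovery_rate = 0.9),
    designs = list(srs = list(strategy = "srs", n = 30),
                   rs = list(strategy = "rs", n = 30)),
    error_levels = list(c(1, 0.01)),
    recovery_levels = list(0.9),
    n_reps = 4, seed = 2,
    pilot_error_rates = list(tpr = 1, fpr = 0.01, recovery = 0.9)),
    cfg, auto_unbox = TRUE)
  sim <- ali_cli(c("simulate", "--config", cfg, "--out", td))
  expect_true(file.exists(file.path(td, "summary.tsv")))
  rec <- jsonlite::read_json(file.path(td, "recommendation.json"),
                             simplifyVector = TRUE)
  expect_true(rec$recommended %in% c("srs", "rs"))
  tab <- utils::read.delim(file.path(td, "summary.tsv"))
  expect_setequal(unique(tab$design), c("srs", "rs", "naive"))
})
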