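# Shared fixtures: tiny hand-built cohorts and quick generator configs.

# a bare-bones cohort data frame with the columns the designs and the SMLE
# need; x_true is carried for oracle checks only
make_cohort_df <- function(y, x_star, z, v = 0L, x_validated = NA_real_,
                           x_true = NA_real_) {
  n <- length(y)
  out <- data.frame(id = seq_len(n), y = y, z = z,
                    x_true = rep_len(x_true, n), x_star = x_star,
                    n_star = 10L, v = rep_len(as.integer(v), n),
                    x_validated = rep_len(x_validated, n),
                    n_validated = NA_integer_)
  class(out) <- c("ali_cohort", class(out))
  out
}

quick_config <- function(n = 500, seed = 1, ...) {
  generator_config(n_patients = n, seed = seed, ...)
}

# the frozen data-quality scenario used for design-comparison checks:
# missingness confined to presumed-unhealthy components (the audit-roadmap
# premise), with the EHR's ordering of missingness — vitals nearly
# complete, metabolic labs moderate, rare inflammation labs worst
scenario_missingness_unhealthy <- function() {
  c(sbp = 0.05, dbp = 0.05, bmi = 0.05, triglycerides = 0.30,
    cholesterol = 0.30, crp = 0.50, hba1c = 0.40, albumin = 0.30,
    creatinine_clearance = 0.30, homocysteine = 0.50)
}

scenario_config <- function(recovery = 0.9, seed = 1, n = 1000) {
  generator_config(
    n_patients = n, tpr = 1.00, fpr = 0.01, missingness = 0,
    missingness_unhealthy = scenario_missingness_unhealthy(),
    recovery_rate = recovery, seed = seed)
}

# indicator vector helper: named 0/1/NA over the ten canonical components
ind <- function(...) {
  base <- stats::setNames(rep(NA_integer_, 10), ali_component_names())
  args <- list(...)
  for (nm in names(args)) base[[nm]] <- args[[nm]]
  base
}
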