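# alivalid

Partial-validation designs and sieve maximum likelihood for measuring
whole-person health — the allostatic load index (ALI) — from error-prone,
incomplete electronic health records (EHR).

## The problem

The ALI condenses ten physiological measurements (blood pressures, BMI,
triglycerides, cholesterol, C-reactive protein, HbA1c, serum albumin,
creatinine clearance, homocysteine) into one number: here, the
**proportion of non-missing components at unhealthy clinical levels**
(0 = best, 1 = worst). In EHR data the components are often missing and
occasionally wrong, so the ALI computed "as is" (call it `X*`) is an
error-prone surrogate for the chart-review-validated ALI (`X`). The
target of inference is a logistic healthcare-utilization model

    logit Pr(Y = 1 | X, Z) = b0 + b1 X + b2 Z,

with `Y` an indicator of hospitalization/ED use and `Z` age per decade
above 18, reported as a baseline odds `exp(b0)`, an odds ratio per
0.1-point ALI increase `exp(0.1 b1)`, and an odds ratio per decade
`exp(b2)`. Only a subsample of `n << N` patients can be chart-reviewed;
the package provides everything needed to design, audit, and analyze such
a two-phase partial-validation study:

* **`ali_core`** — the computable phenotype: clinical thresholds
  (`ali_components()`, `discretize_component()`), the proportion-style
  ALI (`compute_ali()`), and audit-roadmap recovery of missing unhealthy
  components (`apply_roadmap_recovery()`).
* **`synthetic_cohort`** — a generator (`generator_config()`,
  `generate_cohort()`, `apply_validation()`) reproducing the statistical
  structure the methods assume, since the underlying patient data cannot
  be shared.
* **`validation_designs`** — SRS, case-control, balanced case-control,
  optimal stratified, extreme-tail, and residual sampling
  (`sample_*()`), plus multi-wave orchestration that never reselects a
  patient (`run_multiwave()`).
* **`smle_inference`** — the semiparametric sieve maximum likelihood
  estimator (`fit_smle()`): an EM algorithm combining validated and
  unvalidated patients, with a B-spline model for the error mechanism
  `Pr(X | X*)`, profile-likelihood standard errors (`profile_se()`), a
  naive baseline (`fit_naive()`), and prediction of validated ALI for
  unreviewed patients (`predict_validated_ali()`).
* **`audit_tools`** — long-format chart-review tables (`audit_long()`),
  the five mutually exclusive auditor findings (`classify_finding()`),
  TPR/FPR/recovery summaries (`quality_summary()`), and Fleiss' kappa
  (`fleiss_kappa()`).
* **`design_sim`** — the design-selection engine
  (`run_design_comparison()`, `recommend_design()`).
* **`cli_app`** — `run_workflow()` and the `ali_cli()` command-line entry
  point (`inst/cli/ali.R`) wiring generate → design → validate → fit →
  predict.

## Worked example

A synthetic cohort of 1000 patients under the published data-quality
profile (component TPR = 1.00, FPR = 0.01; missingness concentrated on
presumed-unhealthy components; 90% roadmap recovery), validated in the
study's two stages — 52 patients by balanced case-control, then 48 by
residual sampling:

```r
library(alivalid)

cfg <- generator_config(n_patients = 1000, seed = 2024,
  missingness = 0, tpr = 1, fpr = 0.01, recovery_rate = 0.9,
  missingness_unhealthy = c(sbp = 0.05, dbp = 0.05, bmi = 0.05,
    triglycerides = 0.30, cholesterol = 0.30, crp = 0.50, hba1c = 0.40,
    albumin = 0.30, creatinine_clearance = 0.30, homocysteine = 0.50))
cohort <- generate_cohort(cfg)

naive <- fit_naive(cohort)                       # error-prone baseline
pilot <- sample_bcc(cohort, 52, seed = 1)        # balanced case-control
cohort <- apply_validation(cohort, pilot$selected_ids, cfg, seed = 2)
wave2 <- sample_rs(cohort, 48, fit_naive(cohort)$beta, seed = 3)
cohort <- apply_validation(cohort, wave2$selected_ids, cfg, seed = 4)

fit <- fit_smle(cohort, se = TRUE)               # sieve MLE on all 1000
print(fit)
utilization_odds_summary(unname(fit$beta), fit$se)
```

Output:

```
Sieve MLE logistic fit (N = 1000 , validated = 100 )
Converged after 37 EM iterations
              estimate         se    ci_lower   ci_upper
(Intercept) -1.3112660 0.21832740 -1.73918766 -0.8833442
ali          0.6797943 0.48546943 -0.27172580  1.6313144
age_decade   0.1023459 0.05151579  0.00137498  0.2033169

        quantity estimate ci_lower ci_upper
1  baseline_odds    0.269    0.176    0.413
2 or_per_0.1_ali    1.070    0.973    1.177
3  or_per_decade    1.108    1.001    1.225
```

Read: an 18-year-old with ALI 0 has fitted odds 0.27 of engaging the
healthcare system; each additional unhealthy component multiplies the
odds by 1.07; each decade of age by 1.11. (This is one synthetic draw —
with only 100 validated patients the ALI coefficient is noisy; the
generating values were baseline odds 0.23, OR 1.12 per component, 1.11
per decade. The test suite's 500-replicate simulation shows the estimator
centered on the truth while the naive fit is systematically biased.)

The same pipeline is scriptable end to end:

```sh
Rscript inst/cli/ali.R generate --config gen.json --out cohort.tsv
Rscript inst/cli/ali.R design   --cohort cohort.tsv --strategy rs --n 48 \
                                --seed 2 --out design.json
Rscript inst/cli/ali.R validate --cohort cohort.tsv --ids design.json \
                                --config gen.json --out validated.tsv
Rscript inst/cli/ali.R fit      --cohort validated.tsv --se --out fit.json
Rscript inst/cli/ali.R predict  --fit fit.json --cohort validated.tsv \
                                --out predictions.tsv
```

## Documentation

The methods vignette (`vignettes/alivalid-methods.Rmd`) describes the
model and its assumptions, the EM/sieve implementation and its numerical
safeguards, what the synthetic generator does and does not emulate, and
every place a design decision was genuinely open.
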