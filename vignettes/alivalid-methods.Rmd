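---
title: "Measuring whole-person health from imperfect EHR data: methods behind alivalid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring whole-person health from imperfect EHR data: methods behind alivalid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The allostatic load index (ALI) summarizes whole-person health as a
composite of ten physiological components across three body systems
(cardiovascular, metabolic, inflammation). Each component is a binary
indicator that a measurement — systolic/diastolic blood pressure, BMI,
triglycerides, total cholesterol, C-reactive protein, HbA1c, serum
albumin, creatinine clearance, homocysteine — crosses a clinical
threshold. Electronic health records make the ALI computable at scale,
but EHR measurements are *missing* for many patients (labs are only
ordered when clinically indicated) and occasionally *wrong* (extraction
and transcription errors). Treating a missing component as healthy
misclassifies it, so this package defines the ALI as the **proportion of
non-missing components at unhealthy levels**:
\[
X^* \;=\; \frac{\sum_j (1 - M_j^*)\, S_j^*}{\sum_j (1 - M_j^*)},
\]
where \(S_j^*\) is the error-prone component and \(M_j^*\) its
missingness flag.

The scientific question is the association between whole-person health
and healthcare utilization: a logistic model
\[
\operatorname{logit} \Pr(Y = 1 \mid X, Z) = \beta_0 + \beta_1 X + \beta_2 Z,
\]
with \(Y\) an indicator of hospitalization/ED use, \(X \in [0,1]\) the
*validated* ALI, and \(Z\) age coded as \((\text{age} - 18)/10\), so
\(\exp(\beta_0)\) is the baseline odds for an 18-year-old with ALI 0,
\(\exp(0.1\,\beta_1)\) the odds ratio per 0.1-point (one-component) ALI
increase, and \(\exp(\beta_2)\) the odds ratio per decade of age. Chart
review (validation) yields \(X\) for a subsample of \(n \ll N\) patients;
everyone contributes the error-prone \(X^*\).

## The semiparametric sieve maximum likelihood estimator

With validation indicator \(V_i\), the observed-data log-likelihood is

\[
\sum_i V_i\left[\log \Pr_\beta(Y_i \mid X_i, Z_i) + \log \Pr(X_i \mid X^*_i)\right]
+ \sum_i (1 - V_i) \log \sum_k \Pr_\beta(Y_i \mid x_k, Z_i)\,\Pr(x_k \mid X^*_i),
\]

under two assumptions: (i) validation sampling depends only on the fully
observed \((Y, X^*, Z)\), making \(X\) missing at random — every sampling
design in this package conditions only on those quantities, so this holds
*by construction*; (ii) surrogacy: \(Y \perp X^* \mid X\). The support of
\(X\) is the tenths grid \(\{0, 0.1, \dots, 1\}\) by default (exact
observed support available via `support = "observed"`).

The error mechanism \(\Pr(X = x_k \mid X^*)\) is modeled by a sieve:
\(\sum_j B_j(X^*)\, p_{kj}\) with B-spline basis functions \(B_j\)
forming a partition of unity and coefficient columns \(p_{\cdot j}\) on
the probability simplex. Estimation is by EM:

* **E-step.** Unvalidated patients get posterior weights
  \(w_{ik} \propto \Pr_\beta(Y_i \mid x_k, Z_i)\Pr(x_k \mid X^*_i)\);
  validated patients carry point mass at their observed \(X\).
* **M-step.** \(\beta\) solves a weighted logistic regression over the
  patient-by-grid expansion (damped Newton steps that never decrease the
  complete-data objective, i.e. a generalized EM); the sieve update treats
  the basis index as a second latent variable,
  \(p_{kj} \leftarrow \sum_i \phi_{ikj} / \sum_{i,k'} \phi_{ik'j}\) with
  \(\phi_{ikj} = w_{ik} B_{ij} p_{kj} / \sum_{j'} B_{ij'} p_{kj'}\),
  which keeps the observed log-likelihood monotone. (The histogram-style
  closed form \(\sum_i B_{ij} w_{ik}/\sum_i B_{ij}\) is *not* the
  maximizer for overlapping B-splines and demonstrably breaks
  monotonicity.)

Iterations use SQUAREM-style extrapolation with a safeguard: an
extrapolated step is accepted only if it does not decrease the observed
log-likelihood, otherwise the plain EM step is taken. The monotone-trace
invariant is asserted in the test suite. Convergence is declared when the
largest absolute parameter change of a plain EM step falls below `tol`
(default `1e-4`, cap 1000 map applications); probabilities are floored at
`1e-12` inside logarithms.

### Sieve dimension and degree

The corresponding choices of the original analysis are not public, so
the defaults here are the package's own, and one deviates from an obvious
first guess for a documented reason. A cubic sieve with
\(\lceil 2 n^{1/3}\rceil\) basis functions looks natural but proved
systematically biased in simulation: under tail-heavy validation designs
(residual sampling), the globally smooth cubic basis oversmooths an error
mechanism that is nearly degenerate (\(X \approx X^*\) plus a
missingness-driven shift), attenuating \(\hat\beta_1\) by roughly a
quarter of its standard deviation — verified to be a property of the
maximizer itself (multi-start direct maximization finds the same optimum),
not of the EM. The default is therefore a **degree-1 (local linear)
B-spline sieve with \(\lceil 3 n_{\mathrm{val}}^{1/3}\rceil\) basis
functions** — deliberately undersmoothed, as sieve theory for plug-in
functionals recommends. Cubic and histogram (degree-0) sieves remain
available through `degree`/`n_basis`. Conditioning the error mechanism on
\(Z\) as well (`conditioning = "x_star_and_z"`) is available but subject
to the curse of dimensionality at \(n_{\mathrm{val}} \approx 100\); the
default conditions on \(X^*\) only, matching the application.

### Standard errors

SEs come from numerically differentiating the profile log-likelihood
\(\mathrm{pl}(\beta) = \max_p \ell(\beta, p)\), re-maximizing the sieve at
every perturbed \(\beta\). A pilot pass with \(1/\sqrt{N}\) forward
differences sets the scale; the reported pass uses central second
differences with steps of \(0.1\,\mathrm{SE}_j\) per coefficient — the
profile log-likelihood is noticeably non-quadratic beyond \(\sim0.3\) SE
at these validation sample sizes, so larger steps bias the curvature.
Non-positive-definite curvature is reported as a failure, never silently
repaired. With complete validation the machinery reproduces standard
logistic SEs to a few tenths of a percent (tested).

### Predicting validated ALI

For unvalidated patients the fitted error mechanism yields
\(\widehat{E}[X \mid Y, X^*, Z]\) (posterior mean over the grid;
`use_outcome = FALSE` drops the outcome factor). Whether the original
analysis conditioned on \(Y\) for its predicted-ALI figure is not stated
in the main text; conditioning is the default here because it uses all
available information, and both modes are exposed.

## Validation designs

All designs operate on \((Y, X^*, Z)\) only. SRS; case-control (equal
split on \(Y\)); balanced case-control (equal split on the four
\((Y, X^*_D)\) cells, \(X^*\) cut at its within-cohort median by
default); extreme-tail sampling on a fully observed column; residual
sampling (rank by \(r_i = Y_i - \operatorname{expit}(\hat\beta_0^* +
\hat\beta_1^* X^*_i + \hat\beta_2^* Z_i)\) from the naive fit, take the
\(n/2\) most negative and \(n/2\) most positive; odd \(n\) favours the
side with the larger absolute extreme; boundary ties are broken by a
seeded draw); and an optimal stratified design.

The optimal design's allocation criterion is an approximation of our own
(the literature's exact allocation is not reproduced in the source
material): the information gained by validating a patient equals, by
Louis' identity, the posterior variance of their complete-data score
given \((Y, X^*, Z)\); stratum means of these gains enter
\(I(\mathbf{n}) = I_0 + \sum_h n_h \bar{G}_h\), and the allocation
minimizing \([I(\mathbf{n})^{-1}]_{\beta_1\beta_1}\) is found by
exhaustive search (at most four strata), with ties broken toward balance.
The planning error model is a binomial disagreement-count approximation
built from pilot TPR/FPR. The search is cross-checked against an
independent grid evaluation in the tests.

A practical warning surfaced by the simulations: validating *only*
two-tail residual-sampled patients yields a completely separated
validated set (selected cases all have low \(X^*\), selected controls
high \(X^*\)) and destroys the fit. Residual sampling is meant for a
*later wave* on top of a stratified base (the original study used it only
for its final 48 patients after 52 balanced case-control validations);
`run_multiwave()` makes that composition explicit and never reselects a
patient.

## The synthetic cohort: what it emulates and what it does not

Because the study's patient data cannot be shared, every downstream stage
is exercised against a generator whose defaults are the stated world:

* \(N = 1000\) patients, age uniform on 18–65;
* true components Bernoulli with prevalences chosen so the error-prone
  ALI is right-skewed with median \(\approx 0.33\) and roughly six
  non-missing components per patient (matching the cohort's published
  descriptives); these prevalence values are this package's choice, not
  the study's;
* outcome model \(\beta = (\log 0.23,\; 10\log 1.12,\; \log 1.11)\), the
  published final estimates (baseline odds 0.23, OR 1.12 per 0.1 ALI,
  OR 1.11 per decade);
* component misclassification TPR = 1.00, FPR = 0.01 (the published
  preliminary-audit rates);
* per-component missingness, optionally depending on the true component
  value (two rates: healthy vs unhealthy). The default is MCAR within
  component; the design-comparison scenario concentrates missingness on
  *unhealthy* components (vitals 0.05, metabolic labs 0.30, rare
  inflammation labs 0.50, HbA1c 0.40, albumin and creatinine clearance
  0.30) — the audit-roadmap premise is that missing values are presumed
  unhealthy, and it is the only structure under which near-complete
  recovery makes the validated ALI coincide with the true ALI, as the
  published simulation findings require;
* validation corrects errors on observed components and recovers each
  missing, truly unhealthy, anchored component with probability
  `recovery_rate`; serum albumin has no anchors and is never recovered.

What a green test does **not** establish: the generator has no
longitudinal structure, no demographic covariates beyond age, no
encounter-level imputation artifacts (the "extracted value not found"
phenomenon), and its missingness mechanism is a stylized two-rate model.
Conclusions about the real EHR rest on the audit tooling, not on these
simulations.

## Design-comparison engine and its frozen scenario

`run_design_comparison()` shares cohorts across candidate designs within
a replicate (common random numbers — a variance-reduction choice of this
package) and summarizes mean, bias, SD, Monte Carlo SE and efficiency
relative to SRS per scenario. `recommend_design()` matches the scenario
nearest the observed pilot rates (Euclidean distance on
\((\mathrm{TPR}, \mathrm{FPR}, \mathrm{recovery})\)) and returns the
minimum-variance design; ties go to the design with the fewest
assumptions (SRS first — the source text's tie-break phrasing is
self-contradictory, and this is the reading adopted).

The acceptance-level simulation freezes one scenario: the generator above
with recovery 0.9 (and 0.5 for the low-recovery comparison), a balanced
case-control base wave of 52, then 48 more patients by the candidate
design, 500 replicates. Under it, residual sampling is the most efficient
design and the naive estimator is materially biased while the SMLE is
not — the qualitative pattern the methodology predicts. The remaining
small-sample bias of the SMLE under residual sampling (of order a tenth
of its SD) is real and documented rather than tuned away; it shrinks with
a richer sieve and vanishes under SRS.

## Audit tooling choices

Findings are five mutually exclusive categories (correct / incorrect /
not-found for extracted values; auxiliary found / not found for missing
ones). Numeric agreement defaults to exact comparison (tolerance 0) so a
transposed 5.6 vs 6.5 is *incorrect*; a tolerance is configurable.
Entries classified "extracted value not found" (e.g., the vitals imputed
across encounters that auditors could not locate) carry no validated
value and are excluded from TPR/FPR denominators — how the original
analysis handled them is unstated, and this choice is recorded here.
Recovery is `aux_found / (aux_found + aux_not_found)`. Fleiss' kappa is
implemented from the standard per-item/marginal agreement formulas and
tested against an independent arithmetic oracle; a single-category table
has chance agreement 1 and kappa is reported as undefined.

## Numerical and degenerate-input policy

* ALI with all ten components missing is an explicit error, never 0.
* Recovery can only assign "unhealthy" — guidelines exist only for
  presumed-unhealthy missing values.
* The serum-albumin threshold direction follows the printed clinical
  table (≥ 3.5 unhealthy) even though clinical convention is the
  opposite; a config override flips it, and the discrepancy is surfaced
  in the component table's documentation.
* Stratum allocations exceeding stratum size are redistributed
  proportionally to remaining capacity; empty-stratum allocations error.
* A zero mixture probability for an unvalidated patient (support/basis
  misconfiguration) is an error, not a floor.
* Sieve basis cells that receive no data keep their initial coefficients
  and trigger a warning.

## Known limitations

Outcome misclassification is out of scope (exposure error only). The OPT
design's variance criterion is an approximation and is only exact-by-search
for ≤ 4 strata. Profile SEs assume a locally smooth profile likelihood;
at very small validation samples the Wald intervals inherit its
non-quadraticity. The generator's component prevalences and the frozen
simulation scenario are package choices documented above, not published
values.
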