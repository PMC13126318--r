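Package: alivalid
Title: Partial-Validation Designs and Sieve Maximum Likelihood for the
    Allostatic Load Index in Electronic Health Records
Version: 0.1.0
Authors@R:
    person("EHR Methods", "Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to measure whole-person health from error-prone,
    incomplete electronic health records (EHR) via the allostatic load
    index (ALI) computable phenotype. Implements the ALI as a proportion
    of non-missing unhealthy components with a clinician-defined audit
    "roadmap" for recovering missing components; two-phase validation
    sampling designs (simple random, case-control, balanced case-control,
    optimal stratified, extreme-tail, and residual sampling) with
    multi-wave orchestration; a semiparametric sieve maximum likelihood
    estimator (EM algorithm with a B-spline model for the exposure error
    mechanism) that fuses validated and unvalidated data in a logistic
    outcome model; chart-review audit bookkeeping with data-quality
    summaries and Fleiss' kappa; a synthetic-cohort generator; and a
    design-comparison simulation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
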