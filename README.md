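# qbamisclass

Validation-based quantitative bias analysis for misclassified binary
outcomes.

Health outcomes pulled from electronic health records (EHR) — typically the
presence of a diagnostic code — are error-prone classifiers of the true
condition. Analyses that take such a classifier `W` at face value report a
biased prevalence and a biased exposure effect for the true outcome `X`.
This package is for epidemiologists and data scientists who have (or can
assemble) an internal validation subcohort in which `X` was ascertained for
both levels of `W`, and who want to carry the measured misclassification
through to their results instead of caveating it.

## What it computes

**Closed-form bias theory.** With sensitivity SN = Pr(W=1|X=1) and
specificity SP = Pr(W=0|X=0) that do not depend on exposure, the observed
prevalence is

```
p = r·SN + (1−r)·(1−SP)
```

for true prevalence `r`; observed and true prevalence coincide only at the
fixed point `r = (1−SP)/(2−SN−SP)`. The observed relative risk of a binary
exposure is `RR* = (r₁SN + (1−r₁)(1−SP)) / (r₀SN + (1−r₀)(1−SP))`, equal to
1 whenever `r₁ = r₀` and generally attenuated toward the null.

**Validation estimation.** Accuracy parameters are estimated from the
validation subcohort by saturated logistic regressions —
`logit P(X=1|W) = β₀ + β₁W` for the predictive values (PPV, NPV and their
complements FDR, FOR) and `logit P(W=1|X) = α₀ + α₁X` for sensitivity and
specificity (with FNR, FPR). Adding a stratum main effect and interaction
makes every parameter stratum-specific; a 2-df likelihood-ratio test
(`test_differential()`) decides whether misclassification is differential.
Precision comes from case-resampling bootstrap percentile intervals.

**Probabilistic bias analysis.** `simulate_prevalence()` and
`simulate_rr()` propagate the validation uncertainty by Monte Carlo: each
replicate samples the validation coefficients from their fitted
distributions, converts every cohort member's `(W, Z)` into a probability
of true disease, draws potential true outcomes, and (for the RR analysis)
refits a modified Poisson regression with robust variance. The 2.5/50/97.5
percentiles across replicates give the median adjusted estimate and its 95%
simulation interval, optionally likelihood-weighted.

A synthetic cohort generator with known truth (`generate_cohort()`,
`validation_design()`) closes the loop: every estimator is verified by
parameter recovery against cohorts whose misclassification mechanism is
known exactly.

## Worked example

The package ships the complete case study it was built around: an EHR
indicator of chronic hepatitis C infection, validated against chart review
and laboratory confirmation in a 418-patient subcohort.

```r
library(qbamisclass)

fx <- case_study_fixtures()
cross_tabulate(fx$validation)
#> # A tibble: 1 × 5
#>   stratum    tp    fp    fn    tn
#>     <int> <int> <int> <int> <int>
#> 1      NA    47    30     5   336

render_accuracy_table(bootstrap_ci(fx$validation, "classification",
                                   reps = 1000, seed = 1))
#> Sensitivity  90% (82%, 98%)
#> Specificity  92% (89%, 94%)

fit <- fit_validation_model(fx$validation, "predictive")
accuracy_from_fit(fit)
#> # A tibble: 4 × 3
#>   stratum parameter estimate
#>     <int> <chr>        <dbl>
#> 1      NA ppv         0.610
#> 2      NA npv         0.985
#> 3      NA fdr         0.390
#> 4      NA for         0.0147

sim <- simulate_prevalence(fx$risk_based, fit,
                           sim_config(reps = 1000, seed = 42))
sim
#> Misclassification-adjusted prevalence (1000 replicates, seed 42)
#>   median 2.66%  (95% SI: 1.78%, 4.69%)
```

Only 2.0% of the 3,773-patient cohort carried the diagnostic code, and just
1.2% were confirmed — yet the bias analysis puts the plausible true
prevalence around 2.7%: the code's imperfect sensitivity hides roughly as
many true cases among the uncoded as the false-positive codes add.
`autoplot(sim)` draws the full simulated-prevalence density;
`simulate_rr()` does the analogous adjustment for a relative risk under
differential misclassification, and `run_case_study()` regenerates the
entire report bundle (accuracy tables, adjusted prevalence and RR,
per-replicate draws) from the fixtures.

A thin command-line front end wraps the same functions; see
`inst/cli/qba.R` (`qba validate`, `qba adjust-prevalence`, `qba adjust-rr`,
`qba closed-form`, `qba simulate`, `qba case-study`).

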