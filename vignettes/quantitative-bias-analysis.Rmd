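---
title: "Quantitative bias analysis for misclassified binary outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative bias analysis for misclassified binary outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qbamisclass)
```

## The problem

A binary health outcome ascertained from an administrative proxy — here, the
presence of a diagnostic code in an electronic health record — is a
classifier `W` of the true condition `X`, not the condition itself. Its
error structure is fully described by sensitivity SN = Pr(W=1|X=1) and
specificity SP = Pr(W=0|X=0), or equivalently (at a given prevalence) by
the predictive values PPV = Pr(X=1|W=1) and NPV = Pr(X=0|W=0). Analyses
that use `W` in place of `X` report the observed prevalence

$$p = r\,\mathrm{SN} + (1-r)(1-\mathrm{SP}),$$

where `r` is the true prevalence, and an observed relative risk

$$\mathrm{RR}^* = \frac{r_1\mathrm{SN} + (1-r_1)(1-\mathrm{SP})}
                      {r_0\mathrm{SN} + (1-r_0)(1-\mathrm{SP})}$$

under *nondifferential* misclassification (accuracy not depending on the
exposure `Z`). Three consequences drive the package design:

* prevalence can be biased in either direction, and is unbiased only at the
  fixed point `r = (1−SP)/(2−SN−SP)` (`no_bias_prevalence()`), where the
  missed cases exactly balance the false positives;
* `RR*` equals 1 whenever `r₁ = r₀` and equals the true ratio when SP = 1,
  but is otherwise attenuated — and none of this survives *differential*
  misclassification, where SN/SP vary with `Z` and the bias can point
  anywhere;
* standard errors computed from `W` refer to `p`, not `r`.

The closed-form layer (`observed_prevalence()`, `observed_rr()`,
`prevalence_se()`, `predictive_values()`) implements exactly these
identities, vectorized over parameter grids so bias surfaces can be
tabulated.

## Estimating the accuracy parameters from a validation subcohort

Given a subcohort in which `X` was ascertained for both levels of `W`, the
package estimates accuracy by logistic regression rather than by direct 2×2
division:

* predictive form: `logit P(X=1|W) = β₀ + β₁W`, so FOR = expit(β₀) and
  PPV = expit(β₀+β₁);
* classification form: `logit P(W=1|X) = α₀ + α₁X`, so FPR = expit(α₀) and
  SN = expit(α₀+α₁), with SP = 1 − FPR;
* differential forms add `Z` and the `W×Z` (or `X×Z`) interaction, making
  every parameter stratum-specific:
  FOR₀ = expit(β₀₀), FOR₁ = expit(β₀₀+β₀₁), PPV₀ = expit(β₀₀+β₁₀),
  PPV₁ = expit(β₀₀+β₁₀+β₀₁+β₁₁), and analogously for SN/FPR.

Both directions are *saturated* in their regressors: the maximum-likelihood
fitted cell probabilities equal the empirical cell proportions, so the
regression estimates agree with the 2×2 arithmetic to numerical precision
(the test suite asserts agreement to 1e−8, which is why the IRLS
convergence tolerance is tightened to 1e−12). The regression route is
preferred because it composes: bootstrap resampling, stratification, a
likelihood-ratio test for differential misclassification
(`test_differential()`, 2 df), and the coefficient covariance needed by the
Monte Carlo stage all come for free.

Interval estimates use nonparametric case resampling of the whole
validation subcohort with percentile intervals (linear interpolation
between order statistics). Stratified resampling (fixing the `W` margins)
is available as an option but plain case resampling is the default.
Resamples that empty a required cell, or that push a parameter to the 0/1
boundary (detected as a coefficient beyond ±15 on the logit scale), are
redrawn up to 10 times; if more than half the replicates still fail the
data are declared too sparse to bootstrap. For genuinely sparse or
separated validation data the fits accept `method = "firth"`, a
Jeffreys-prior penalized likelihood implemented as a Newton iteration on
the hat-adjusted score; it yields finite interior estimates where plain
maximum likelihood diverges.

## The probabilistic bias analysis

`simulate_prevalence()` implements the nondifferential algorithm. Per
replicate:

1. draw the predictive-model coefficients — by default each from an
   independent normal with its fitted mean and variance
   (`coefficient_sampling = "independent"`); a joint multivariate-normal
   option using the full covariance is provided and is statistically
   preferable when the coefficients are strongly correlated, and `"none"`
   fixes the coefficients to isolate the Bernoulli noise;
2. convert each cohort member's `w` into π = expit(β̇₀ + β̇₁w);
3. draw a potential true outcome X· ~ Bernoulli(π) for every member whose
   `x` is unknown (members with a validated `x` keep it by default;
   `keep_observed_x = FALSE` simulates everyone);
4. record the cohort mean of the (kept + simulated) outcomes.

The 2.5/50/97.5 percentiles over replicates are the median adjusted
prevalence and its 95% simulation interval. This is a sensitivity analysis
over scenarios consistent with the data and the validation model, not a
deterministic correction: each replicate is one plausible realization of
the truth.

`simulate_rr()` extends this to a relative risk under possibly differential
misclassification: π comes from the four-coefficient differential
predictive model and `(w, z)`; each replicate's simulated outcomes are fed
to a modified Poisson regression of X· on `Z` with HC0 robust variance
(`fit_modified_poisson()`); estimation noise is then added by drawing
log RR̈ from normal(log RR·, var(log RR·)). The variance in that draw is
the sandwich variance of the *log*-RR coefficient — drawing log-scale noise
with an RR-scale variance would be dimensionally ill-defined. Replicates
with no simulated cases in an exposure stratum have an undefined RR; they
are dropped and counted, with a warning above 20% dropped.

### Likelihood weighting, honestly

As a guard against implausible realizations, the RR summaries can
additionally be weighted by each replicate's Poisson model likelihood
(`weighting = "likelihood"`). Weights are exp(loglik − max loglik),
normalized — the standard underflow-safe construction. Two caveats belong
in the open. First, each replicate's likelihood is evaluated on *its own*
simulated outcomes, so the weights compare models across different
pseudo-data. Second, when the spread of replicate log-likelihoods is large
(tens of units, as in the shipped case study, where the number of simulated
cases varies substantially across replicates), the exponentiation
concentrates essentially all weight on a handful of replicates and the
weighted interval collapses toward single draws. The weighted median is
still reported — it lands inside the unweighted simulation interval, which
is the property the tests assert — but the unweighted summary is the
primary result, and the weighting should be read as the stopgap it is
rather than a resolution of the plausibility problem. A full treatment
would be Bayesian and is out of scope.

### Reproducibility mechanics

All randomness flows from one integer seed. The master seed draws a vector
of per-replicate substream seeds, so extending a run from 500 to 1,000
replicates leaves the first 500 replicates bit-identical — a property the
tests assert. Simulated outcomes are drawn per person (not collapsed to
binomial counts) so the keep-observed and simulate-all modes share one code
path.

## The synthetic cohort generator

`generate_cohort()` embodies the same data-generating mechanism the theory
assumes: Z ~ Bernoulli(pz), X ~ Bernoulli(r_Z),
W ~ Bernoulli(SN_Z) if X = 1 and Bernoulli(1 − SP_Z) otherwise.
Misclassification depends only on `(X, Z)` — dependent misclassification
(error probabilities that depend on other misclassified variables) is
deliberately not modeled. `validation_design()` then masks `X` outside a
validation scheme: either "all classifier-positives plus k sampled
negatives" (the design of chart-review studies, and of the shipped case
study) or a simple random fraction. Both schemes sample ignorably given
`W`, matching the exchangeability assumption under which the predictive
model estimated on the subcohort transports to the full cohort.

What passing the recovery tests shows: with the mechanism as assumed, the
estimators recover SN/SP/PPV/NPV, the adjusted prevalence recovers the
cohort's realized true prevalence (the estimand is the prevalence in the
cohort at hand, so coverage is judged against realized mean(X), not the
superpopulation rate), and a null RR is recovered under strongly
differential misclassification that inflates the naive RR. What it does
not show: robustness to non-exchangeable validation sampling, to
dependent misclassification, to covariate-dependent accuracy beyond one
binary `Z`, or to selection and confounding biases — none of which the
generator emulates.

## The case-study fixtures

The package ships, generated in code, the validation study it was built
around: a 418-record validation subcohort (cells 47/30/5/336), the
race-stratified validation counts as printed (the published cells were
inflated 100-fold for stratified stability and are used exactly as
printed), and a 3,773-record main cohort with 77 classifier-positives
whose validated outcomes (47 confirmed / 30 refuted) are retained. The
race split of the main cohort by classifier status was never published;
the fixture carries a *reconstructed* split (16 coded White / 61 coded
non-White, consistent with the published margins and yielding the
published naive RR of 1.73), documented as such — RR results on this
fixture are internal consistency checks, not reproductions. Two printed
stratified values (PPV₁ and SN₀) are mutually inconsistent with the
printed stratified cells; the package reports the values the cells imply
(68% and 76%).

Worth knowing: with the default `keep_observed_x = TRUE` the adjusted
prevalence for this cohort has median ≈ 2.7% with a 95% simulation
interval of roughly (1.8%, 4.7%); simulating all members instead widens
the interval to roughly (1.3%, 5.0%) with the same median. The published
analysis is compatible with the second convention; the medians agree
either way, and the package keeps the known outcomes by default because
discarding validated truth is hard to defend outside a sensitivity
analysis.

## Numerical and design choices

* Percentiles: type-7 (linear interpolation) for unweighted summaries; the
  weighted quantile is the smallest draw whose cumulative normalized weight
  reaches the target.
* Rounding happens only at the reporting layer (`render_accuracy_table()`),
  half-up to match conventional percent tables; all core functions return
  full-precision proportions.
* Robust variance: HC0 without small-sample correction — the estimator's
  standard form, and the simulation averages over replicates anyway.
* Binary coding is fixed at 0/1 in the data layer; label recoding (e.g.
  race categories) happens once at CSV read time via an explicit map.
* Test problem sizes are the package's own balance of precision and
  runtime: the type-I-error check of the differential test runs 400
  simulated cohorts of n = 4,000; bootstrap stability is checked at 2,000
  replicates; end-to-end interval coverage at 50 seeds × 300 replicates on
  cohorts of n = 6,000; parameter recovery at n = 50,000.

## Limitations

Beyond the generator's assumptions listed above: the validation models
condition on a single binary stratum variable (more covariates are a
mechanical but data-hungry extension); prevalence adjustment under
*differential* misclassification additionally requires the covariate
distribution and is not provided; the likelihood weighting caveats above;
and exact logistic regression is not offered (Firth penalization covers
the sparse-data need).
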