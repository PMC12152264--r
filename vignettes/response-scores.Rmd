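---
title: "Individualized response scores for progression trials: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized response scores for progression trials: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rshte)
```

## The statistical model

A two-arm trial records, for each patient, baseline covariates and a
time-to-confirmed-progression outcome. The package's central object is the
**response score**: a per-patient linear predictor on the log hazard-ratio
scale,

$$ \mathrm{RS}(x) = \beta_0 + \sum_j \beta_j \, t_j(x_j), $$

interpreted as the individual log hazard ratio of treatment versus control
given the patient's transformed baseline profile $t(x)$. More negative
scores predict larger treatment benefit. A patient is a **responder** when
their score falls at or below a threshold; two conventions are supported:
the first quartile of the training-score distribution (used while ranking
candidate models) and the log of the whole-group hazard ratio (used for
validation and for the packaged clinical-practice scores).

The slopes are constructed by fitting one Cox prognostic model per arm and
differencing the coefficients (`method = "two_fit"`, the default), or
equivalently in large samples from the treatment-by-covariate interaction
terms of a single pooled Cox model (`method = "pooled"`). In both cases the
intercept is the treatment main effect of the pooled interaction model with
*uncentered* covariates, so the score has the same functional form as the
published clinical-practice formulas: an intercept plus raw covariate
terms.

### Covariate transforms

Transforms are registered per term (see `variable_set()`): identity for
age, EDSS and relapse count, a male indicator for sex, and **base-10**
logarithm for disease duration. Base 10 matters: the packaged score
fixtures only reproduce their published worked examples under
$\log_{10}$, not the natural log.

## Confirmed-progression outcomes

`derive_progression()` converts visit-level scores into four time-to-event
outcomes:

* **EDSS**: worsening of at least 1.0 point when baseline EDSS $\le 5.0$,
  0.5 point otherwise;
* **T25FW** and **9HPT**: worsening of at least 20% from baseline
  (inclusive);
* **SDMT**: a drop of at least 4 points (inclusive).

A qualifying worsening becomes an event only when *confirmed* at a later
visit at least one window away (84 days by default; 168 days for SDMT), by
default with the worsening sustained at every intermediate visit
(`sustained = FALSE` relaxes this to endpoint-only confirmation). The event
time is the *initial* qualifying visit, not the confirming one. An
unconfirmed worsening is censored at the last visit.

## Model selection and validation

`select_response_score()` runs the full sequence:

1. split the cohort 70:30 into training and validation sets (the training
   size is `round_half_up(0.7 n)`, so 1,645 patients split 1,152/493),
   with a Cohen's d balance table (|d| > 0.10 flagged);
2. enumerate **all $2^p - 1$ non-empty covariate subsets**
   (`enumerate_subsets()`, capped at 20 variables);
3. for each subset, build the score on the training set, classify at the
   training first quartile, estimate the treatment hazard ratio separately
   in responders and non-responders, and rank ascending by the
   responder/non-responder HR ratio;
4. carry the top-ranked convergent candidate to the validation set,
   classify at the log whole-group HR, and declare it **validated** when
   the HR ratio is below 0.80 and/or the treatment-by-responder
   interaction p-value is below 0.20. The liberal 0.20 level is
   deliberate: interaction tests are low-powered, and the criterion is a
   screen rather than a confirmatory test.

Performance is profiled with the AD(q) curve (`adq_curve()`: the treatment
HR re-estimated inside the best-scoring fraction q, whose value at q = 1
equals the overall HR by construction), calibration tables across score
quartiles (`calibration()`), bootstrap replicability of the whole
selection-plus-validation loop (`replicability()`), and conditional
permutation variable importance (`variable_importance()`), which permutes
each variable within strata of its correlated covariates (|r| > 0.2,
quartile bins) so that correlated variables cannot borrow importance from
one another.

Missing baselines are completed by chained-equation imputation
(`mice_impute()`): ten cycles of conditional Bayesian regressions with
posterior-predictive draws, logistic for sex, with counts and EDSS rounded
back to their supports. Estimates across completed datasets combine with
Rubin's rules (`pool_rubin()`).

## The synthetic trial generator

Because the motivating trial data are proprietary, the package ships a
generator (`synthetic_trial_config()`, `simulate_trial()`) that emulates a
progressive-MS cohort:

* **n_patients = 1645**, 2:1 treatment:control allocation;
* age truncated-normal (mean 48, sd 8, range 18–60); 60% female; EDSS on
  the 3.0–6.5 half-point grid with most mass at 6.0–6.5; relapse counts
  Poisson(0.7); disease duration log-normal (median 12 years) truncated to
  [0.5, 45];
* event times are exponential proportional-hazards draws with arm-specific
  log-hazards `log_rate_arm + X beta_arm`, anchored so a reference profile
  reaches a target event fraction (25–35% per outcome by default) within
  720 days of administrative censoring, plus 10% uniform dropout;
* treatment-arm coefficient offsets define the ground-truth heterogeneity.
  Built-in worlds: `"table2"` (defaults mimicking the published
  coefficient patterns), `"null"` (no treatment effect at all), and
  `"average_only"` (a uniform hazard ratio, `overall_hr`); arbitrary
  per-outcome truths can be injected via `hte`;
* `visits = TRUE` additionally materializes visit-level score
  trajectories on a 90-day grid. Event times are first **snapped to the
  visit grid** (up to the next visit; events whose confirmation visit
  would fall beyond follow-up become censorings), so that with zero
  trajectory noise `derive_progression()` reproduces the simulated event
  table *exactly* — a round-trip identity the test suite asserts.
  Increasing `trajectory_noise` corrupts the derived outcomes
  monotonically.

The generator's truth is recorded per outcome (`$truth`), and
`true_response_score()` evaluates it on any baseline table, which is what
makes parameter-recovery and discrimination tests possible.

### Generator limitations

The generator is deliberately simple: hazards are exponential (no shape
over time), outcomes are drawn independently given covariates (no
cross-outcome correlation), covariates are drawn independently of each
other, and trajectory noise is additive white noise on the visit grid.
It is built for *testing identifiability and calibration of the
machinery*, not for clinical realism.

## Numerical conventions

* **Rounding**: all printed scores and hazard ratios use
  `round_half_up()` — ties go toward $+\infty$ (`floor(x * 100 + 0.5) /
  100` at 2 decimals). This is the convention under which the packaged
  fixtures reproduce their published worked-example displays; R's
  `round()` (banker's rounding) does not.
* **Cox fits**: `survival::coxph()` with Efron ties, convergence
  tolerance $10^{-9}$, up to 100 iterations; non-convergence is flagged
  and excludes a candidate from ranking rather than silently passing
  through.
* **Intercept recovery**: the score intercept is the log HR at
  transformed covariate value 0 — an extrapolation far outside the
  covariate support (age 0, EDSS 0). Its sampling error is an order of
  magnitude larger than any slope's even at n = 20,000, so recovery
  tests check the slopes and the score at the *mean covariate profile*
  instead; both are estimable at desk scale.
* **Determinism**: every stochastic routine takes an explicit seed, and
  child seeds derive from the master seed by a fixed affine map, so whole
  pipeline reports (`run_pipeline()`) are bit-reproducible and embed a
  hash of their effective configuration.

## Problem sizes used in the test suite

The packaged suites run at desk scale on one CPU: worked-example and
arithmetic checks are instantaneous; null calibration uses 500 simulated
trials of n = 2,000 (~1 min); parameter recovery uses one trial of
n = 20,000 with widened covariate spread and an 85% event fraction
(seconds); selection consistency uses 50 trials of n = 4,000 with a
planted EDSS modifier (~1 min); AD(q) ordering compares two matched
worlds of n = 10,000. The full suite completes in a few minutes.

## Known limitations

* The all-subset search is exhaustive and exponential; it is capped at 20
  variables and intended for small clinical variable sets.
* The HR-ratio ranking statistic is noisy in small strata; candidates
  whose strata cannot be estimated are ranked last rather than dropped.
* The AD(q) area is a mean curve height on the HR scale over the
  evaluable grid; it is a relative diagnostic for comparing worlds or
  scores, not an absolute effect estimate.
* Imputation runs the analysis on the first completed dataset (with the
  imputation count recorded); fully pooled selection across completed
  datasets is out of scope.
* With heavily tied discrete scores, calibration quantile bins can
  collapse; empty bins are reported as not evaluable rather than
  silently merged.

## A worked session

```{r worked, eval = FALSE}
# score three illustrative patients with the packaged published models
worked_examples()

# simulate, select and validate end-to-end
cfg <- pipeline_config(synthetic = synthetic_trial_config(n_patients = 800),
                       outcomes = "EDSS", variables = c("age", "edss"),
                       seed = 1)
report <- run_pipeline(cfg)
report$outcomes$EDSS$verdict$validated
```
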