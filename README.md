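# rshte

Individualized response scores for treatment-effect heterogeneity in
two-arm time-to-progression trials.

## The science

Average treatment effects hide variation: in a trial with an overall
hazard ratio of, say, 0.79, some patient profiles may benefit far more
and others not at all. This package implements a response-score approach
to that problem for confirmed-disability-progression outcomes of the
kind used in progressive multiple sclerosis trials (EDSS, Timed 25-Foot
Walk, 9-Hole Peg Test, SDMT):

1. **Score construction.** Fit a Cox prognostic model of the outcome on
   baseline covariates *separately in each arm*; the difference of the
   two coefficient vectors, plus the treatment main effect of a pooled
   interaction model, defines a per-patient linear **response score** on
   the log hazard-ratio scale. `exp(score)` is the patient's predicted
   individual hazard ratio; lower means more predicted benefit.
2. **All-subset selection.** Enumerate every non-empty subset of a small
   clinical variable set (age, sex, prior relapses, disease duration,
   EDSS), build a candidate score per subset on a 70% training split,
   and rank candidates by how strongly they separate the treatment
   effect between predicted responders (best-scoring training quartile)
   and non-responders.
3. **Hold-out validation.** On the remaining 30%, classify patients at
   the log of the whole-group hazard ratio and call the score
   *validated* when the responder/non-responder HR ratio is below 0.80
   and/or the treatment-by-responder interaction p is below 0.20.
4. **Profiling.** AD(q) discrimination curves, calibration by score
   quartile, bootstrap replicability of the entire selection loop, and
   conditional permutation variable importance.

The package also ships the four published clinical-practice score
formulas as fixtures, a synthetic trial generator with known ground-truth
heterogeneity (so every estimator can be tested against truth), a
confirmed-progression derivation engine for visit-level data, and
chained-equation imputation for missing baselines. See the vignette
(`vignettes/response-scores.Rmd`) for methods details and numerical
conventions.

## Worked example

Three illustrative patients scored with the packaged published models and
classified at the published whole-group HR cut-offs:

```r
library(rshte)
worked_examples()
```

```
 patient_id outcome score   hr score_full         label
  patient_1    EDSS -0.19 0.83 -0.1900000 non_responder
  patient_1    9HPT -0.11 0.89 -0.1150000 non_responder
  patient_1   T25FW -0.24 0.79 -0.2406530     responder
  patient_1    SDMT -0.33 0.72 -0.3315682     responder
  patient_2    EDSS -0.33 0.72 -0.3300000     responder
  patient_2    9HPT -0.16 0.85 -0.1650000     responder
  patient_2   T25FW  0.22 1.24  0.2156086 non_responder
  patient_2    SDMT  0.19 1.21  0.1896910 non_responder
  patient_3    EDSS -0.47 0.63 -0.4700000     responder
  patient_3    9HPT -0.24 0.79 -0.2400000     responder
  patient_3   T25FW -0.66 0.52 -0.6571957     responder
  patient_3    SDMT -0.41 0.67 -0.4051545     responder
```

Patient 1 (55-year-old woman, EDSS 3, five relapses in two years, three
years' duration) is predicted to benefit on walking speed and processing
speed but not on EDSS or dexterity; patient 3 (30-year-old woman, EDSS 2,
six relapses, two years' duration) is a predicted responder on all four
outcomes.

An end-to-end run on simulated data:

```r
cfg <- pipeline_config(synthetic = synthetic_trial_config(n_patients = 800),
                       outcomes = "EDSS", variables = c("age", "edss"),
                       seed = 1)
report <- run_pipeline(cfg)
report$outcomes$EDSS$selected_subset
report$outcomes$EDSS$verdict$validated
```

## Repository layout

This repository is an analysis workflow: the package code in `R/` is
driven by numbered scripts in `analysis/` which write plain-text tables
to `results/`:

```sh
Rscript analysis/01_simulate_trial.R    # simulate and persist the trial
Rscript analysis/02_derive_outcomes.R   # re-derive outcomes from visits
Rscript analysis/03_fit_scores.R        # fitted vs published coefficients
Rscript analysis/04_select_validate.R   # all-subset selection + validation
Rscript analysis/05_evaluate.R          # AD(q), calibration, importance
Rscript analysis/06_worked_examples.R   # the three-patient table above
```

## Reproduction

The acceptance targets (the worked-example scores and hazard ratios) are
recomputed from the installed package by:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

which evaluates the packaged published response scores on the two fully
printed example patients and writes one `{"value": ..., "n": ...}` entry
per target. All targets are deterministic closed-form evaluations; the
seed only fixes the session state.
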