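# vpmrecal

Validation and recalibration of the Vienna Prediction Model (VPM) for
recurrent venous thromboembolism (VTE).

## What this package is for

After a first *unprovoked* VTE, stopping anticoagulation trades a
recurrence risk against a bleeding risk. The VPM scores that recurrence
risk from three predictors measured after anticoagulation withdrawal —
sex, site of the index event (isolated distal DVT / proximal DVT /
pulmonary embolism) and D-dimer — via a Cox model:

```
lp   = b_male·[male] + b_prox·[proximal DVT] + b_PE·[PE] + b_log2D·log2(D-dimer)
risk = 1 − S0(t)^exp(lp),    points = a + b·lp
```

Patients at or below 180 points (a predicted 1-year risk of at most
5.5%) are classified low risk. `vpmrecal` is for biostatisticians running
the *prospective validation* of such a model on a new cohort and the
*model update* when it is miscalibrated:

* per-patient scoring, classification and risk surfaces
  (`vpm_score()`, `risk_surface()`);
* Kaplan-Meier cumulative recurrence incidence with Greenwood plain-scale
  bands, actuarial and person-time rates, one-sample threshold z-tests
  (`kaplan_meier()`, `actuarial_interval_rate()`, `person_time_rate()`,
  `threshold_z_test()`);
* external-validation metrics: calibration slope (Cox coefficient on the
  model's linear predictor; ideal 1.0), observed/expected event ratio
  with bootstrap CI, Uno's IPCW concordance, grouped calibration
  (`validate_model()`);
* model updating: offset lack-of-fit test of the predictor weights,
  Breslow baseline-hazard recalibration (after which O/E = 1 exactly),
  bootstrap percentile bands, Harrell optimism-corrected O/E
  (`recalibrate()`);
* a synthetic-cohort generator matched to published cohort summaries and
  a simulation-based power calculation for threshold designs
  (`generate_study_like()`, `simulate_power()`).

Everything takes a tidy cohort tibble first and returns tibbles (or small
S3 objects with `tidy()`/`glance()`/`autoplot()` methods), so stages
chain with the pipe.

The shipped default model (`vpm_definition()`,
`inst/extdata/vpm_default_synthetic.yaml`) is a **synthetic** stand-in
weight set — the published VPM constants are not redistributed. Supply a
transcription of the real constants as a YAML config via
`read_vpm_definition()` to score against the actual model.

## Worked example

```r
library(vpmrecal)

model  <- vpm_definition()                     # synthetic default weights
cohort <- generate_study_like(seed = 42, n = 520)

report <- run_study_pipeline(cohort, model, n_boot = 1000, seed = 42)
report
#> <vpm_study_report> n = 520 patients, seed = 42
#>   cumulative incidence: 6.1% at 12 mo (95% CI 4.0-8.2), 11.3% at 24 mo (95% CI 8.5-14.1)
#>   threshold tests: p = 0.035 (vs 8%), p = 0.124 (vs 13%)
#> <vpm_validation> n = 520, events = 56, horizon = 24 months
#>   calibration slope: 0.63 (95% CI -0.02-1.28)
#>   O/E: 56 / 46.5 = 1.20 (95% CI 0.92-1.52)
#>   Uno's c (tau = 24): 0.569
#> <vpm_recalibration>
#>   lack of fit: chi-square = 8.25 (df 4), p = 0.0827
#>   recalibrated baseline: S0(24) = 0.9934
#>   optimism-corrected O/E: 1.02 (95% CI 0.78-1.35), 1000 resamples
```

Reading the output: this simulated 520-patient cohort had a 6.1%
(95% CI 4.0-8.2) observed 1-year cumulative recurrence incidence, so the
one-sided test against the 8% design threshold gives p = 0.035. The O/E
of 1.20 means the scored model under-predicted events by 20% overall;
after Breslow recalibration of the baseline hazard the internally
validated (optimism-corrected) O/E is 1.02 — calibration-in-the-large is
restored, and the bootstrap interval quantifies how much of that is
resampling optimism. The lack-of-fit test (p = 0.083) finds no clear
evidence that the predictor *weights* themselves need modification.

Plots: `autoplot(report$curve)` (cumulative incidence with dashed bands),
`autoplot(report$validation$calibration)` (observed vs predicted by risk
quintile), `autoplot(risk_surface(report$recalibration$model))`
(risk vs D-dimer by sex and site).

## Cohort file format

Delimited text (comma default, tab accepted), header row, columns:
`patient_id, sex, site, ddimer_ng_ml, time_months, event, end_reason`
and optionally `excluded_before_assessment`. See `?validate_cohort` for
levels and invariants; `read_cohort()`/`write_cohort()` round-trip
losslessly.

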