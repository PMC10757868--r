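---
title: "Validating and recalibrating a VTE recurrence risk model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and recalibrating a VTE recurrence risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpmrecal)
```

## The problem

Patients whose first venous thromboembolism (VTE) was unprovoked face a high
risk of recurrence after anticoagulation is stopped, but extended
anticoagulation exposes them to bleeding. The Vienna Prediction Model (VPM)
is a Cox-model based score that estimates an individual's recurrence risk
from three predictors measured after anticoagulation withdrawal: sex, the
site of the index event (isolated distal DVT, proximal DVT, or pulmonary
embolism) and D-dimer. Patients at or below a points threshold — 180 points,
corresponding to a predicted 1-year recurrence risk of 5.5% — are candidates
for stopping anticoagulation.

`vpmrecal` implements the full statistical workflow for *prospectively
validating* such a model on a new cohort and *updating* it when it is
miscalibrated:

1. per-patient scoring: linear predictor, nomogram points, predicted
   cumulative risk, low/high classification;
2. nonparametric estimation of the observed cumulative recurrence
   incidence (Kaplan-Meier, actuarial second-year rate, person-time rates)
   and one-sample threshold z-tests;
3. external-validation metrics: calibration slope, observed/expected (O/E)
   event ratio, Uno's censoring-robust concordance, grouped calibration;
4. model updating: an offset lack-of-fit test for the predictor weights,
   Breslow re-estimation of the baseline hazard, bootstrap percentile
   confidence bands, and Harrell's optimism-correcting bootstrap for the
   updated model's O/E;
5. a synthetic-cohort generator and a simulation-based power calculation,
   so every stage is exercisable without access to patient data.

## The model

For patient $i$ with covariates $x_i$ the linear predictor is

$$
lp_i = \beta_{male}\,[\text{male}] + \beta_{prox}\,[\text{proximal DVT}]
     + \beta_{PE}\,[\text{PE}] + \beta_{log2D}\,\log_2(\text{D-dimer, ng/mL}),
$$

with female sex and isolated distal DVT as reference levels. The predicted
cumulative recurrence risk at $t$ months is $1 - S_0(t)^{\exp(lp_i)}$, and
the nomogram points score is the affine map
$\text{points} = a + b \cdot lp$ with $b > 0$. `vpm_definition()` stores all
of these together and enforces that the points gate (180) and the 1-year
risk gate (5.5%) denote the same patients; a score of exactly 180 points is
low risk.

The numeric constants of the originally published VPM are not
redistributed in this package. The shipped default
(`vpm_definition()` with no arguments, also in
`inst/extdata/vpm_default_synthetic.yaml`) is a **synthetic** weight set:
effect directions and magnitudes plausible for this disease area
($\beta_{male} = 0.6$, $\beta_{prox} = 0.5$, $\beta_{PE} = 0.6$,
$\beta_{log2D} = 0.25$, constant baseline hazard
$2.3\times10^{-4}$/month), with the points intercept solved so the
threshold correspondence holds exactly. Every function takes the model as
an explicit argument, so a transcription of the published constants can be
supplied as a YAML config via `read_vpm_definition()` without touching any
code.

## Survival estimation choices

* **Kaplan-Meier confidence bands** are symmetric normal-approximation
  intervals on the probability scale (Greenwood variance), truncated to
  $[0,1]$. The plain scale was chosen over log or complementary log-log
  because symmetric bands are the ones a threshold z-test reconstructs
  from a printed interval; published low-risk VTE cohort intervals are
  symmetric, consistent with this convention.
* **Threshold z-tests** use $z = (\hat p - p_0)/\widehat{se}$ with the
  Greenwood standard error of the Kaplan-Meier estimate at the horizon and
  a one-sided lower-tail p-value. Reconstructing the standard error from a
  printed symmetric 95% interval, $(\text{hi}-\text{lo})/(2\cdot 1.96)$, is
  equivalent.
* **Ties**: events precede censorings at tied times (standard
  product-limit convention). The censoring-distribution Kaplan-Meier used
  by Uno's weights applies the mirrored rule.
* **Actuarial interval rate**: life-table conditional probability
  $d/(n - c/2)$, treating within-interval censorings as half-exposed.
* **Person-time rates** are per 100 person-years (1 year = 12 months)
  with exact Poisson intervals by chi-square inversion; exact intervals
  are conservative and remain valid at the small event counts typical of
  second-year strata.

## Cox fitting, O/E, and why recalibrated O/E is exactly 1

Cox models are fitted by partial likelihood with the Efron tie correction
(month-scale follow-up makes ties likely); offsets enter the linear
predictor with coefficient fixed at 1. Fitting is delegated to
`survival::coxph()` behind `fit_cox()`; the package's own tests verify the
returned coefficient against a brute-force grid maximization of the
hand-written partial likelihood, so the wrapper's contract is checked
independently of the fitting engine.

The Breslow baseline estimator with fixed linear predictors places an
increment $d_t / \sum_{j \in R(t)} e^{lp_j}$ at each distinct event time.
It satisfies the martingale identity
$\sum_i \hat H_0(\min(t_i, h))\, e^{lp_i} = \#\{\text{events} \le h\}$
exactly. For this reason the package defines the **expected** event count
of the O/E ratio on the cumulative-hazard scale,

$$ E = \sum_i \hat H_0(\min(t_i, \text{horizon}))\, e^{lp_i}, $$

so each subject accrues expected events only over their own follow-up
(censoring cannot inflate $E$), and a model whose baseline has just been
Breslow-recalibrated on the same cohort has $O/E = 1$ to machine
precision — the anchor property used throughout the bootstrap internal
validation. At the low event probabilities this model operates on,
$H_0 e^{lp}$ and $1 - S_0^{\exp(lp)}$ differ only in the third decimal, so
this choice is numerically immaterial for realistic cohorts but makes the
recalibration identity exact rather than approximate.

Uno's concordance is implemented directly from its definition: comparable
pairs $(i, j)$ with $t_i < t_j$, $t_i < \tau$ and $i$ an event, weighted by
$\hat G(t_i)^{-2}$ where $\hat G$ is the censoring-distribution
Kaplan-Meier. Without censoring it reduces to Harrell's C, which is how it
is tested (brute-force pair counting). $\tau$ defaults to the 24-month
study horizon. A zero censoring-survival weight raises an error advising a
lower $\tau$ rather than returning an unstable estimate.

## Recalibration and internal validation

The updating sequence follows the validation-study playbook:

1. **Lack-of-fit test**: refit the model's own four covariates with the
   existing linear predictor as an offset. The fitted coefficients are the
   *suggested modifications* to the published weights (zero under perfect
   fit); a likelihood-ratio test with 4 df tests whether any modification
   is needed. A warning is issued below 5 events per free parameter.
2. **Baseline recalibration**: weights are left untouched; the baseline
   survival is replaced by $\exp(-\hat H_0)$ from the Breslow estimator.
   The points gate stays primary and the equivalent 1-year risk gate is
   re-derived under the new baseline.
3. **Bootstrap bands**: patients are resampled with replacement
   (the resampling unit is the patient row), the baseline re-estimated per
   resample, and pointwise 2.5/97.5 percentiles of the cumulative baseline
   risk taken on a monthly grid. Pointwise (not simultaneous) bands are
   computed. Zero-event resamples are redrawn and counted.
4. **Optimism-corrected O/E** (Harrell): the apparent O/E of the
   recalibrated model is exactly 1; each resample's recalibrated model is
   evaluated on the resample and on the original cohort, and the mean
   apparent-minus-test gap is subtracted. The correction is applied on the
   O/E scale directly (not log O/E); at O/E values near 1 the two scales
   agree to first order, and the percentile interval of the corrected
   replicates is reported either way.

All bootstrap operations require an explicit seed and are bit-reproducible
given (seed, number of resamples, cohort order).

## The synthetic-cohort generator

Because patient-level data from validation studies of this kind are
typically not deposited, the generator is a first-class module: it defines
the *study conditions* under which the pipeline is exercised and tested.

* **Covariates**: sex Bernoulli(0.56); site categorical
  (0.17, 0.40, 0.43); D-dimer lognormal with median 280 ng/mL and
  log-scale sigma fitted to the printed quartiles (190, 450):
  $\sigma = \text{mean}\{\ln(450/280), \ln(280/190)\}/0.6745 \approx 0.639$.
  Because the printed IQR is not exactly symmetric on the log scale, the
  implied quartiles are about 182 and 431 ng/mL — within 5% of the printed
  values; the median is matched exactly. D-dimer is rounded to 10 ng/mL to
  mimic assay reporting (switchable).
* **Event process**: piecewise-exponential proportional hazards. The
  two-segment baseline hazard (0-12, 12-24 months) is *solved
  numerically* — by quadrature over the covariate distribution — so the
  population mean cumulative incidence hits 5.2% at 1 year and 11.2% at
  2 years (the "study-like" preset) or 4.4%/8.3% (the "historical" preset
  used for power calculations). Event times are drawn by inverse transform
  on $H_0(t)e^{lp}$.
* **Censoring**: administrative at 24 months plus exponential premature
  dropout with rate $-\ln(1 - 68/520)/24 \approx 0.0057$/month,
  matching 68 premature study endings among 520 patients over 24 months;
  premature end reasons are drawn in the proportions 56/1/1/10
  (anticoagulation restart / death from other cause / withdrawal / loss to
  follow-up).

What the generator does **not** emulate: the joint (conditional)
distribution of D-dimer given sex and site in a real cohort, enrolment
over calendar time, competing mortality, and measurement drift between
assays. Self-consistency results on synthetic cohorts therefore
demonstrate the correctness of the estimators and the updating machinery,
not the clinical performance of any particular weight set on real
patients.

## Power calculation

`simulate_power()` reproduces the design calculation of threshold studies:
trials of `n_per_trial` patients are resampled with replacement from a
reference cohort; each trial's Kaplan-Meier estimate at the horizon is
tested against the null threshold at a one-sided 2.5% level, and power is
the rejection fraction with simulation standard error
$\sqrt{p(1-p)/n_\text{trials}}$. With the historical preset
(1-year incidence 4.4%) and 500 patients per trial against an 8%
threshold, simulated power lands in the low-to-mid 90s — consistent with
published design calculations for this configuration; the exact value
depends on the reference cohort's censoring structure, which is not
recoverable from printed summaries. A trial whose Kaplan-Meier estimate is
undefined at the horizon counts as a non-rejection (conservative).

## Numerical and interface choices

* Quantiles everywhere are type-7 (linear interpolation), the default of
  the analysis environment this workflow targets; printed-style
  percentages round half-up to integers.
* Cohorts are ordinary tibbles with a fixed schema
  (see `?validate_cohort`); files are UTF-8 delimited text, comma by
  default with tab accepted. Eligibility screening is represented only as
  a pre-assessment exclusion flag — the package accounts for patient flow,
  it does not adjudicate eligibility.
* The points/risk threshold consistency is enforced at `1e-6`; Cox
  convergence at gradient tolerance `1e-9` with at most 100 Newton
  iterations; collinear or constant covariates and monotone-likelihood
  non-convergence raise errors or flags rather than returning silently.
* Problem sizes used in the shipped checks were chosen to keep Monte
  Carlo error well below the tolerances being asserted: n = 50,000 for
  closed-form survival comparisons, n = 5,000-6,000 for 3-standard-error
  parameter-recovery checks, 100-replicate batches for null-distribution
  checks, and 1000-trial power runs.

## Known limitations

* The default model is a labelled synthetic stand-in, not the published
  weight set; conclusions about the *actual* VPM require supplying its
  constants.
* The O/E confidence interval uses a percentile bootstrap over patients;
  published intervals for such ratios do not always state their method,
  so exact agreement with any specific publication's interval is not
  guaranteed.
* No competing-risks estimation: death other than from recurrence is
  treated as censoring, which is the convention of the validation design
  this package mirrors but can overstate absolute risk in older
  populations.
* Time-varying covariates, stratified baselines and penalized updating
  are out of scope.

## A worked example

```{r example, eval = FALSE}
model <- vpm_definition()
cohort <- generate_study_like(seed = 42, n = 520)

report <- run_study_pipeline(cohort, model, n_boot = 1000, seed = 42)
report
autoplot(report$curve)
autoplot(report$validation$calibration)
autoplot(risk_surface(report$recalibration$model))
```
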