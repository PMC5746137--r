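---
title: "Renal adjustment of serum HE4 and deep-myometrial-invasion risk models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Renal adjustment of serum HE4 and deep-myometrial-invasion risk models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(he4ren)
```

## The problem

HE4 (human epididymis protein 4) is a serum tumour biomarker used in
gynaecologic oncology. Because it is cleared from circulation by
glomerular filtration, its serum concentration rises when kidney function
declines — a purely renal effect that masquerades as tumour signal. In
endometrial cancer, where HE4 elevations are often subtle, this renal
inflation matters, and so does HE4's resulting apparent age dependence
(kidney function declines with age).

This package implements two connected pieces of methodology:

1. **HE4ren**, a renal adjustment that projects an observed HE4 value to
   its equivalent at an eGFR of 90 ml/min/1.73 m², removing the
   filtration component; and
2. **risk models for deep myometrial invasion (dMI)** — tumour invading
   at least half of the uterine muscle wall — in grade 1-or-2 endometrial
   cancer, built on HE4ren together with age, histological grade and
   CA125. dMI status guides whether lymphadenectomy and referral to a
   tertiary surgical centre are warranted.

The clinical cohorts behind the published coefficients are not publicly
deposited, so the package pairs the models with seeded synthetic-cohort
generators whose mechanisms are the package's own models run forwards.
Everything downstream of generation is exercised exactly as it would be
on real data.

## The renal adjustment

In non-cancer controls, ln(HE4) rises approximately linearly as eGFR
falls below 90 ml/min/1.73 m², and is flat above. The model is a
single-basis piecewise regression

$$\ln(\mathrm{HE4}) = \alpha + \beta \cdot \min(\mathrm{eGFR} - 90,\ 0) + \varepsilon,$$

fit by least squares (`fit_piecewise_loglinear()`). The knot is fixed at
90, not estimated, and the zero slope above the knot plus continuity at
it are imposed by the basis itself rather than by fitting two free
segments — the adjustment formula is exactly a knot-anchored projection,
so the constrained parameterisation is the one whose coefficient the
formula needs. The fitted magnitude is reported on a $\times 10^2$ scale
with the sign convention that HE4 *rises* as eGFR falls; the published
adjustment constant is 2.182, frozen as `HE4REN_SLOPE`. The transform is

$$\mathrm{HE4ren} = \exp\!\left[\ln(\mathrm{HE4}) + 2.182 \times (\mathrm{eGFR} - 90) \times 10^{-2}\right]$$

for eGFR ≤ 90 and the identity above 90 (`he4ren()`). Natural logarithms
are used throughout; a base-10 reading would silently change every
downstream probability. Refitting the slope from a control cohort is
supported, but the frozen published constant is the reference behaviour
so that the risk models reproduce their published coefficients.

eGFR itself is computed from age and serum creatinine with the CKD-EPI
2009 creatinine equation, female coefficients, without race adjustment
(`egfr_ckd_epi_female()`); creatinine is taken in µmol/l and converted
internally with the divisor 88.4. No cap at 90 is applied in computation
— clinical laboratories often report ">90", but capping would destroy
the knot logic, so any capping is left to the reporting layer. Only the
female equation is implemented, and male input is rejected explicitly:
every cohort in scope is female, and silently mis-handling sex would be
worse than an error. The analytic inverse
(`creatinine_from_egfr_female()`) back-solves creatinine from a target
eGFR, selecting the branch by comparing the target with the
branch-boundary eGFR at that age; targets whose solution falls outside
1–5000 µmol/l are rejected as clinically meaningless.

## The dMI risk models

**Continuous model.** For grade 1-or-2 patients,

$$P(\mathrm{dMI}) = \frac{1}{1 + e^{\,15.2 - 0.1\,\mathrm{age} - 2.1\,\ln(\mathrm{HE4ren}) - 0.9\,(\mathrm{grade}-1)}}$$

(`predict_dmi_continuous()`, coefficients frozen in
`DMI_CONTINUOUS_COEF`). Grade enters as the numeric term (grade − 1),
which is binary on the grade 1-or-2 cohort. Grade-3 patients are managed
as a high-risk group upstream; the model refuses them and
`classify_cohort()` routes them to the high-risk class with an
annotation instead of a probability. The working probability cut-off
between low- and high-risk is 25%; the training-optimal cut-off by
maximal sensitivity + specificity for this model is 43%.

**Model development.** `fit_logistic_backward()` implements binary
logistic regression with backward elimination: the candidate with the
largest Wald p-value above the stay criterion (α = 0.1) is removed and
the model refit, until all retained p ≤ 0.1. Wald tests and Wald 95%
CIs are used for elimination and reporting; ORs are the exponentiated
coefficients. Ties in the elimination p-value are broken by removing the
predictor with the smaller absolute standardised effect
(|coefficient| × predictor SD), making the procedure deterministic.
Zero-variance candidates are dropped up front with a log entry;
complete separation raises an error naming the offending predictor;
rows with missing candidate values are dropped with a logged count.
When CA125 is offered as a continuous candidate it enters
log-transformed (natural log), mirroring HE4's treatment — a modelling
choice of this package, configurable by passing the untransformed
column instead.

**Categorical model and points system.** The binary risk factors are
grade 2, HE4ren ≥ 45 pmol/l, CA125 ≥ 35 U/ml and age ≥ 60 years — all
boundaries inclusive (`categorize_patient()`). A points system assigns
each factor its logistic coefficient × 10, rounded to one decimal
(`derive_score_model()`); a total score S maps back to probability via
logit(P) = intercept + S/10 (`score_to_probability()`), exact up to the
rounding of the scores. The simplified weights band the factors into
minor (1), intermediate (2) and major (3) by ranking their scores —
lowest 1, highest 3, middle 2 — which reproduces the published
assignment grade→1, HE4ren and CA125→2, age→3 whenever the published
significance ordering holds; the published weights are the frozen
default. A weighted sum ≥ 4 is high-risk (`simplified_risk_class()`),
encoding the 25% probability cut-off. The published categorical model's
own fitted intercept is not publicly available, so the score↔probability
mapping is validated as a self-consistency property (a total score of
27.1 corresponds to 25% exactly when the intercept satisfies the
mapping), not against an external constant.

## Evaluation machinery

AUC is computed through the Mann–Whitney midrank identity, ties counted
½, and is tested against a brute-force all-pairs oracle. Classification
at a cut-off is inclusive (score ≥ cutoff ⇒ positive), consistent with
the inclusive biomarker cut-offs; PPV/NPV are flagged undefined rather
than silently dropped when a denominator is zero. `optimal_cutoff()`
maximises sensitivity + specificity over a grid defaulting to whole
percents 1%–99% (the scale on which the published cut-offs 43%, 33% and
25% live), breaking ties toward the larger cut-off — favouring
specificity — with the tie flagged. The Spearman correlation is the
Pearson correlation of midranks. Percentiles use linear interpolation
between order statistics (`stats::quantile` type 7); the convention is
fixed and documented because reference percentiles of a 66-subject
cohort are convention-sensitive.

## The synthetic cohorts

`generator_config()` fixes the study conditions; `generate_controls()`
and `generate_ec_cohort()` are deterministic given the seed.

* **Age**: normal(65, 8) truncated to [40, 90] years.
* **eGFR**: 130 − 0.9·age + normal(0, 12), clipped to [15, 120] — the
  age coupling is what makes raw HE4 age-correlated, as in real cohorts.
* **Creatinine** is back-solved from the drawn eGFR, so the pipeline's
  own eGFR computation is exercised (and recovers the drawn value to
  machine precision).
* **Baseline HE4**: log-normal, ln-scale normal(ln 45, 0.35),
  independent of age — the latent renally independent value. The
  observed HE4 inflates it below the knot by
  exp(−0.02182·(eGFR − 90)), the exact inverse of the adjustment, so
  generate→adjust recovers the latent baseline to 1e-9 and the
  noise-free limit recovers the slope 2.182 exactly.
* **Grade**: multinomial (0.45, 0.367, 0.167) with 1.7% recorded as
  missing (the printed percentages sum to 100.1% after rounding and are
  renormalised exactly). Rows with missing recorded grade still receive
  an outcome through a latent grade, and are excluded from model fits
  with a logged count.
* **dMI**: Bernoulli with probability from the published continuous
  model on (age, latent HE4ren, grade) for grades 1–2 — so refitting on
  generated data is parameter recovery with known truth — and a fixed
  configurable probability (default 0.55) for grade 3, for which no
  published mechanism exists.
* **CA125**: log-normal, ln-scale normal(ln 17, 0.6), with an additive
  ln-scale shift of +0.5 in dMI-positive patients; setting the shift to
  0 emulates cohorts in which CA125 carries no dMI signal. The base law
  is calibrated to the cohort median; the configured shift inflates the
  marginal median above it, so the calibration target applies to the
  dMI-negative stratum.

These parameters are calibrated only loosely to the emulated cohort's
medians and interquartile ranges and are modelling choices, exposed in
the configuration. The generators do **not** emulate inter-centre assay
differences, serum-versus-plasma matrix effects, menopausal-status
structure, or the real control cohort's eGFR distribution — so passing
tests demonstrate the machinery's correctness and internal consistency,
not the clinical performance figures, and the published reference value
of 46.6 pmol/l (95th percentile of HE4ren in CKD-positive controls) is
not reproducible from synthetic data. What *is* checked distributionally
is the analogous invariance: after adjustment, the 95th percentile of
HE4ren in CKD-positive synthetic controls equals the 95th percentile of
the baseline law itself.

## Numerical choices and degenerate inputs

* The piecewise fit requires ≥ 3 subjects and ≥ 2 distinct eGFR values
  at or below the knot; an all-above-knot cohort is a no-information
  error, and a singular design is reported as such.
* `he4ren()` returns the observed value bit-identically above the knot
  (no exp/log round trip), making the identity exact.
* HE4 below 10 pmol/l (the assay's validated linearity bound) warns but
  does not error; creatinine outside 20–1500 µmol/l likewise warns.
* Backward elimination requires at least 10 events and 10 non-events.
* The CKD flag on controls defaults to eGFR < 60, configurable — the
  exact definition used for the published control subgroup is not
  publicly stated, so the threshold is an explicit assumption.
* Problem sizes in the test suite: 66-subject control cohorts (500
  replicates for CI coverage, 200 for the age-correlation property),
  training/validation cancer cohorts of 120/240, a 20 000-patient
  cohort for coefficient recovery, and 1 000 replicates of 5 000
  patients for the elimination false-retention rate. These sizes give
  Monte-Carlo error comfortably inside the asserted bands.

## Known limitations

* The published categorical model's coefficients and intercept are not
  publicly available; the package freezes the published cut-offs,
  weights and threshold, and can refit the categorical model on data,
  but cannot reproduce the original's internal parameters.
* No plasma-to-serum HE4 conversion (plasma runs higher; no published
  factor), no CKD staging beyond the threshold flag, no ROMA/RMI
  indices, no survival or lymph-node endpoints.
* Wald inference throughout; profile-likelihood CIs are not implemented.
* The simplified classifier is published for grade 1-or-2 patients only,
  and this package deliberately does not extrapolate it to any-grade
  cohorts.
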