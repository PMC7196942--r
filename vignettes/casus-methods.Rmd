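---
title: "CASUS: scoring, flow modelling and prognostic evaluation — methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CASUS: scoring, flow modelling and prognostic evaluation — methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casus)
```

## The scale

The carotid artery stenosis ultrasound scale (CASUS) grades each
extracranial supply vessel — bilateral common carotid (CCA), internal
carotid (ICA) and vertebral (VA, segments V1–V3) arteries — on a five-level
ordinal scale from duplex ultrasound: no stenosis (0), mild `<`50 % (1),
moderate 50–69 % (2), severe 70–99 % (3), occlusion (4). When a vessel
carries several stenotic segments the narrowest one governs
(`vessel_ss()`). The patient-level **total stenosis score (TSS)** is the sum
over the six bilateral vessels, range 0–24; applying the identical rule to
CTA/MRA readings gives the radiological-imaging total (**RI-TSS**). The
**global blood flow (GBF)** is the sum of the measured volumetric flows
(mL/min) of the four vessels whose flow the ultrasound protocol records
(bilateral ICA and VA); an occluded vessel has no measurable flow and
contributes 0 by convention.

Two vessel-set conventions therefore coexist: the score sums six vessels,
the flow sums four. Both sets are arguments of `score_patients()`, so a
four-vessel score (range 0–16) is available; the defaults follow the
definitions above.

Grade boundaries are half-open — `[50, 70)` moderate, `[70, 100)` severe,
exactly 100 occlusion — and 0 % (or absence of plaque) is grade `none`,
since the category labels define no numeric lower bound. Near-occlusion is
not distinguished: any vessel below 100 % with detectable flow grades
severe at most. Missing vessels score as `none` with a warning
(`strict = TRUE` turns this into an error); a missing *flow* on a
non-occluded flow-contributing vessel is never imputed.

## The calculated stenosis score

The scale is validated against hemodynamics through the *calculated*
stenosis score: for each vessel type, a grade's mean flow reduction
(no-stenosis mean minus grade mean, `bf_reduction()`) divided by the
mild-grade reduction, which is the reference and scores exactly 1
(`calculated_ss()`). Occlusion is fixed at 4. The statistic is
scale-invariant in the flows and reported at one decimal, half-up;
its nearest integer is the *approximate* score. The package ships the
per-grade flow chart (`casus_flow_chart`) and reproduces the published
chart with `stenosis_score_chart()`:

```{r}
stenosis_score_chart()
```

Percentages throughout are reported at one decimal, half-up
(`round_half_up()`, `percent_of()`), matching clinical reporting style.
`sd_of_change()` implements the standard systematic-review imputation
`sqrt(sd1² + sd2² − 2·corr·sd1·sd2)` for the spread of a change from
baseline; the correlation defaults to 0.5, a common conservative choice,
and should be set explicitly whenever a better estimate exists.

## Flow–score curve models

Flow falls with the score roughly linearly per vessel (`fit_linear()`) and
non-linearly at the whole-brain level. `fit_cubic()` fits
`GBF = b0 + b1·TSS + b2·TSS² + b3·TSS³` by ordinary least squares and
reports R² = 1 − SSE/SST (a constant outcome fits as its mean with R² = 0
by convention) plus the overall-F p-value. `eval_cubic()` evaluates printed
coefficient sets without refitting.

`fit_segmented()` models the inverse-S relationship — an initial sharp
decline, a collateral-compensated plateau, and a second decompensated
decline — as three independent polynomials on `TSS < t1`,
`t1 ≤ TSS ≤ t2`, `TSS > t2`, searching candidate pairs (default: all
integer pairs `3 ≤ t1 < t2 ≤ 12`). No continuity constraint is imposed at
the breakpoints. Two numerical choices matter and are deliberate:

* **Segments never saturate their score levels.** A segment's polynomial
  order is capped at (distinct scores − 2). An interpolating segment has
  zero lack of fit whatever the data, so an uncapped search simply rewards
  whichever partition isolates the sparsest score ranges.
* **Selection uses the df-adjusted pooled R².** Capping makes candidate
  pairs spend different parameter counts, and the expected SSE of a
  correct model is (n − p)·σ²; maximising the plain pooled R² therefore
  systematically favours the most parameter-hungry partition. The search
  maximises `1 − (SSE/(n−p)) / (SST/(n−1))`, reporting the plain pooled
  R² (`1 − ΣSSE/SST`) for the selected pair. Ties break toward the
  smaller first threshold, then the smaller second.

A consequence of the order cap is that a segmentation with very short
segments can score below the single cubic; the nesting guarantee (pooled
R² at least the global cubic's) holds whenever every segment supports a
full cubic.

**Identifiability limitation.** With integer scores and continuous
piecewise structure, a candidate pair that merely reassigns a junction
cell (e.g. `(6,10)` versus `(5,10)` when the plateau spans scores 5–10) fits
the truth *exactly* as well in expectation: the junction cell lies on both
regimes. Moreover a cubic absorbs all but a few percent of a slope-only
corner, so at realistic flow noise (per-vessel SDs of ~30–75 mL/min) the
criterion differences among neighbouring pairs are far below their
sampling fluctuation at n = 750. Exact breakpoint recovery from a cohort
of that size is thus a property of strong or noise-free signals, not of
the default noise level; the package's tests verify exact recovery on
noiseless three-regime data and on deterministic-flow cohorts, and treat
the breakpoints from noisy cohorts as estimates with ±1–2 points of
wobble.

## Prognostic evaluation

Follow-up endpoints are assessed at days 30, 90 and 180 (default 180, the
final assessment): the primary endpoint is recurrence of symptomatic
stroke; secondary endpoints are all-cause death and the composite of
recurrent stroke, cardiac death and non-fatal myocardial infarction.
`classify_endpoints()` reduces an event table to binary
by-horizon flags; a death terminates the record, cause of death must be
labelled in the input (never inferred), and non-cardiac death does not
enter the composite. Patients lost to follow-up before the horizon with no
qualifying event are flagged and excluded from that horizon's denominators;
by construction their exclusion never changes the set of counted events.

`auc_mann_whitney()` computes the AUC in its rank (Mann–Whitney) form —
concordant case–control pairs count 1, ties 0.5 — with the Hanley–McNeil
standard error; the tests verify exact agreement with brute-force pair
counting and with the trapezoidal area under the empirical ROC curve.
`compare_auc_delong()` implements the DeLong placement-value test for
paired (correlated) AUCs, with coincident ROC curves reported as
difference 0, p = 1; it is cross-checked in the tests against an
independent implementation and a studentized sign-swap permutation oracle.
The DeLong p-value is asymptotic: at very small n (a handful of patients)
it can differ materially from the exact permutation law, whose n = 6
distribution has only 64 atoms — agreement to Monte-Carlo error is only
observed from moderate sample sizes upward.

`best_prediction_point()` returns the observed score maximising Youden's
J = sensitivity + specificity − 1, breaking ties toward the smallest
qualifying threshold (mirroring integer clinical cutpoints) and warning
when no threshold beats chance. Risk direction is explicit: higher TSS and
RI-TSS are riskier; lower GBF is riskier, so GBF is negated internally and
its reported threshold is a lower bound.

`evaluate_predictors()` assembles the full report — AUC, SE, normal 95 %
CI clipped to [0, 1], best prediction point, and the conventional
accuracy flag AUC ≥ 0.7 — for every predictor × endpoint, plus all
pairwise DeLong comparisons on the patients with both predictors
available. Endpoints with no events at the horizon are skipped with a
warning. No time-to-event modelling is attempted: prognosis is evaluated
by horizon-binary ROC only.

## The synthetic cohort generator

No patient-level data are distributable, so `generate_cohort()` creates
cohorts with the statistical structure the pipeline assumes, and the
configuration defaults *are* the emulated study conditions:

* **Cohort size** 750 patients; 2.4 % lost to follow-up (uniform censoring
  day).
* **Grade prevalences** put ~87 % of ICA/VA vessels in a stenotic grade
  (none/mild/moderate/severe/occlusion = 0.13/0.44/0.24/0.13/0.06), with a
  milder CCA mix (0.50/0.32/0.12/0.05/0.01); the per-grade split within
  "stenotic" is a modelling choice — no published breakdown exists.
* **Flows** per vessel and grade are Normal with the chart means and SDs
  (`casus_flow_chart`), truncated at zero; occlusion forces flow 0.
  Within-patient fluctuations are negatively equicorrelated (ρ = −1/3,
  marginal SDs unchanged): autoregulation partially redistributes flow, so
  one vessel running low is offset by the others.
* **Whole-brain compensation.** Each patient's planned flow sum is
  regulated toward T(TSS) = (quadratic trend of the grade-implied flow
  sum) + a centred compensation kink (`compensation_curve()`): zero below
  the plateau, +56 mL/min per point recovered across scores 5–10
  (about 90 % of the natural per-point loss, so the plateau declines only
  gently), and an extra 90 mL/min per point (accelerating by 6 per point²)
  once compensation is exhausted above 10. Regime transitions sit between
  integer scores (at 4.5 and 10.5), since the plateau is the score *set*
  {5,…,10}. A few alternating adjustment sweeps reconcile the two
  constraints the generator promises: every vessel–grade cell mean equals
  its chart value, and every patient's planned sum tracks the inverse-S
  set point.
* **Events.** Each endpoint (recurrent stroke 7.7 %, all-cause death
  5.2 %, non-fatal MI 3.4 % at 180 days) follows an independent logistic
  model in TSS. `calibrate_event_model()` sets the slope from the binormal
  approximation `AUC ≈ Φ(slope·sd(TSS)/√2)` (design AUC 0.75 by default)
  and solves the intercept by root-finding so the expected incidence
  matches the target to 1e-6. Event days are uniform on 1–180; deaths are
  cardiac with probability 16/39 and truncate later events.
* **Angiographic re-grades** disagree with ultrasound by one category with
  probability 0.10.

A single integer seed governs the run through per-stage sub-streams, so
outputs are byte-identical across repeats. The generator emulates summary
structure only: it has no ultrasound physics, no velocity criteria, no
competing-risks machinery, no covariate structure beyond TSS, and its
event types are conditionally independent given TSS — so passing tests
demonstrate the pipeline's statistical correctness on data of this shape,
not clinical validity on real cohorts.

## Problem sizes and determinism in the test suite

The suite fixes every stochastic seed. Cohort-scale checks use n = 750
(the emulated enrolment) for parameter-recovery assertions, n = 4000 for
null-AUC checks, and a single n = 20000 run for law-of-large-numbers
calibration checks (incidences within ±0.01, design AUC within ±0.02).
Breakpoint-recovery assertions use noiseless three-regime data and
deterministic-flow cohorts, per the identifiability analysis above.
`scripts/acceptance.R` recomputes the calculated-stenosis-score chart from
the packaged flow table at run time.

## Known limitations

* Whether the study's TSS summed six or four vessels is ambiguous in the
  source material (the printed no-stenosis flow sum of the four measured
  vessels, 1181.2 mL/min, is below the printed cubic intercept 1380.6,
  hinting that more vessels may contribute to GBF than stated); both
  vessel sets are configurable and the defaults follow the definitions.
* The printed cubic equations are not usable beyond their intercepts (one
  is non-monotone where a decline is described, the other lists two linear
  terms); the package treats them as display artefacts and fits its own
  models.
* Breakpoint recovery from noisy integer-score data is identifiable only
  up to junction-cell reassignment (±1), as analysed above.
* The DeLong comparison is asymptotic; for very small samples an exact
  permutation test should be preferred.
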