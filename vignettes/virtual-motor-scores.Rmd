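---
title: "Virtual motor scores and the motor-follows-sensory rule: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual motor scores and the motor-follows-sensory rule}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmscore)
```

## The model

ISNCSCI grades sensation (light touch, LT, and pinprick, PP; 0/1/2) in 28
dermatomes and motor function (0–5) in 10 key myotomes per side. `vmscore`
works on a canonical 29-segment scale `C1 < … < C8 < T1 < … < T12 < L1 < …
< L5 < S1 < S2 < S3 < S45` (S4 and S5 merged, as on the ISNCSCI
worksheet). The 18 segments that are dermatomes but not key myotomes —
C2–C4, T2–L1, S2–S4/5 — receive a *virtual motor score* predicted from the
segment's own sensory scores, after which the motor level is computed by
the same scan as the sensory level: the most caudal segment graded ≥ 3
such that every rostral segment is graded 5.

Three predictor families are implemented:

* **Clinical model (CLM)** — the consensus rule generalized from the
  transition-zone convention: 5 if LT = PP = 2, 0 if LT = PP = 0, else 1
  (single-modality variants: 5/1/0 for scores 2/1/0). It is a fixed
  transfer function and is never fitted.
* **Linear regression (MLR)** — ordinary least squares of the motor score
  on the feature set. The package ships the published coefficient sets
  (`published_models()`), e.g. `0.18 + 1.22·LT + 0.96·PP` for the
  ipsilateral LT+PP set, and fits new ones with `fit_mlr()`.
* **Random forest regression (RFR)** — `ranger` with seeded fitting and
  impurity importances normalized to sum to one. Published forest *cell
  values* are deliberately not hard-coded as a model: forest outputs
  depend on hyperparameters that are not part of the published record, so
  forests exist in this package only as objects you fit yourself
  (`fit_rfr()`). The published importances are available as reference
  metadata.

Feature sets are `ILT`, `IPP`, `ISens` (ipsilateral LT+PP) and `ICSens`
(both sides' LT+PP). Virtual scores for level determination are restricted
to ipsilateral sets: the motor-follows-sensory rule is ipsilateral by
definition, and a contralateral predictor would change the question being
asked, not the answer to it.

Because inputs are integers, every predictor is fully described by a
lookup table of 3, 9 or 81 rows (`lookup_table()`); raw predictions are
reported unclamped, and the `rounded` column — `floor(x + 0.5)` clamped to
0–5 — is what enters level determination.

### Why rounding is half-up

"Mathematically rounded to the nearest integer" with a decisive threshold
at 4.5 is what makes the single-modality linear models unable to produce a
5 (their maxima, 4.34 and 4.45, sit just below it) while the ipsilateral
LT+PP model's 4.54 at (2,2) just clears it. Banker's rounding (R's
`round()`) would send 2.5-adjacent values the wrong way; `round_half_up()`
is therefore implemented as `floor(x + 0.5)` on the non-negative score
scale.

## Level determination and its edge conventions

The level scan walks C2 → S45 and stops at the first segment graded below
5; if that segment is graded 3 or 4 it takes the level, otherwise the
previous segment does. Three conventions are not fixed by the rule itself
and were decided as follows:

* **Fully intact side.** The motor/sensory level of a side with all
  scores normal is reported as the sentinel `INT`, ordered one past S45
  (index 30). Reporting S45 instead would make "intact" indistinguishable
  from a genuine S45 level and would distort shift arithmetic.
* **Rostral sentinel.** If already C2 is graded below 3, the level is C1.
  A C2 grade of 3 or 4 takes the level at C2 itself: it satisfies "≥ 3"
  and has no rostral segment to violate.
* **Not-testable (NT) scores.** Levels are only computed when they are
  determinate: an NT score at or rostral to the candidate level raises a
  classified error (`vmscore_error_indeterminate`) rather than guessing.
  NT scores caudal to the stopping point are irrelevant and allowed.

## Detecting sensory-determined motor levels

The cohort analysis must isolate exactly those sides where sensory
function determined the motor level (levels inferred from the sensory
level, including the transition zones C4/C5 and L1/L2). The detection
procedure replaces every sensory score with a normal score, recomputes the
motor level, and flags the side if the temporary level differs from the
true one. With normal sensation all virtual scores become 5, so the
temporary level is driven by examined muscles alone — any difference
proves the sensory contribution.

`analyze_shift()` computes, per included side, the shift
`index(recalculated) − index(true)` in segments (T12 → L1 counts as one
segment). Sides are analyzed independently — an exam contributes up to two
records — because the underlying rule is per-side; pooling to one record
per exam would discard the information of bilateral asymmetry. Quartiles
and the IQR use the default linear-interpolation quantile estimator
(type 7).

For any ipsilateral model whose lookup table rounds to 5 only at (2,2),
the shift is provably confined to {0, +1}: the model's chain of virtual 5s
coincides with the clinical model's chain (both require intact
sensation segment by segment), so the recalculated scan stops either at
the same segment or — when the first sub-intact segment's prediction
rounds to 3 or 4 — exactly one segment later. The test suite asserts this
on generated cohorts, and asserts that substituting the clinical model
reproduces the true level everywhere.

## Fitting and evaluation

Training rows are segmental triplets: one row per exam, side and key
myotome with the examined motor score and the segment's ipsilateral and
contralateral sensory scores; rows with any NT among the five scores are
dropped (`extract_triplets()`).

Cross-validation (`cv_config()`) defaults to **5 folds × 5 repeats,
grouped by patient, seeded**. The grouping keeps all longitudinal exams of
one patient in a single fold — repeated exams of the same person are
highly correlated, and splitting them across folds would leak outcome
information and flatter every model. R² and RMSE are computed on held-out
rows only, with the held-out fold's own variance as the R² reference; the
reported `±` is the standard deviation over the 25 fold×repeat
evaluations. A zero-variance held-out fold scores R² = 1 when predicted
exactly and `NA` otherwise (the convention of the common regression
toolkits). The clinical model participates in evaluation as a fixed rule
applied to the held-out fold, never fitted.

RFR defaults: 100 trees, unrestricted depth, impurity importances, one
thread, explicit seed — chosen as the common defaults of the underlying
libraries; all exposed as arguments.

`fit_mlr()` raises a classified singular-fit error when fewer than two
distinct feature tuples are present or the design matrix is rank
deficient, rather than returning aliased coefficients.

### Parameter recovery and the censoring caveat

`simulate_linear_triplets()` generates ground-truth data with conditional
mean `0.2 + 1.2·LT + 1.0·PP` and Gaussian noise (σ = 1). Its `clip`
argument decides how the 0–5 score range is enforced, and the choice
matters:

* `clip = "mean"` (default for the recovery benchmark) clips the
  conditional mean before noise — a no-op for these parameters, whose mean
  range [0.2, 4.6] already lies inside [0, 5] — so OLS recovers the
  generating coefficients; at n = 10,000 the fit lands within ±0.05.
* `clip = "response"` censors the noisy response at the bounds. This is
  *not* innocuous: censoring pulls both tails toward the interior and
  attenuates fitted slopes by roughly 0.1 at these parameter values, an
  order of magnitude above sampling error at n = 10,000. A property test
  documents the attenuation. Real integer motor scores are bounded by
  construction rather than by censoring a latent Gaussian, so the
  unbiased reading is the appropriate benchmark; the censored variant is
  kept as a cautionary tool.

## What the synthetic generator emulates — and what it does not

`generator_config()` defines the study conditions of a simulated cohort.
Defaults, chosen once and frozen:

* **Lesion band mix** (`nli_band_probs`): high cervical 25.2%, low
  cervical 25.0%, thoracic 41.6%, lumbosacral 7.2%, sacral 0.2%, intact
  0.8% — the neurological-level distribution reported for a large
  European SCI cohort, with each patient's sensory level drawn uniformly
  within the band. Sacral levels are capped at S3: a drawn level of S4/5
  would require all 28 dermatomes intact and collapse into the intact
  sentinel, consistent with the continuous C1–S3 motor level range.
* **Severity mix** (`severity_probs`): complete 42%, sensory-incomplete
  12%, weak motor-incomplete 14%, strong motor-incomplete 32%, mirroring
  an A/B/C/D impairment-grade split. Severity controls the sensory score
  distribution below the lesion and whether motor scores are zero
  (complete, sensory-incomplete) or drawn from the conditional
  distribution (motor-incomplete). An AIS-like label derived from
  severity is attached as metadata only — it is never computed from the
  generated scores.
* **Transition zone** (`transition_len_probs`): 0–3 segments of mixed
  sub-intact sensory scores immediately caudal to the level
  (probabilities 0.30/0.35/0.25/0.10), reflecting that lesions are rarely
  knife-edge.
* **Motor–sensory coupling** (`ms_given_sens`): a 9 × 6 conditional table
  P(MS | LT, PP) used below the level for motor-incomplete severities.
  The default cell means rise approximately linearly in (LT, PP) — the
  regime in which a linear virtual-score model is the right description —
  with mass concentrated at 5 for intact sensation and at 0 for absent
  sensation. The weak severity reweights each row toward low grades.
  These defaults were calibrated once so that, on the default cohort, a
  fitted ipsilateral LT+PP linear model has positive coefficients and a
  cross-validated R² inside [0.5, 0.8] and beats the clinical rule, then
  frozen; they are conditions for exercising the pipeline, not estimates
  of any clinical cohort's coupling.
* **Longitudinal structure**: each patient keeps one lesion band and
  level across `exams_per_patient` exams (default 3, matching a
  several-exams-per-patient registry structure), with each sub-maximal
  score below the level gaining one point with probability
  `improvement_rate = 0.08` from exam to exam — a deliberately simple
  stand-in for neurological recovery.
* **NT injection** (`nt_rate = 0.01`): not-testable scores are injected
  only caudal to every level-critical segment, so every generated exam is
  classifiable by construction while the NT code paths in extraction and
  I/O still get exercised.

What the generator does **not** emulate: zones of partial preservation,
non-monotone or multi-level lesion patterns, left–right severity
asymmetry beyond a one-segment level jitter, examiner error, the
acute-to-chronic stage structure of registry follow-ups, and any
particular cohort's exact triplet frequencies. Consequently, passing
pipeline tests on generated cohorts demonstrates the *logic* of the
two-step analysis (identities, bounds, orderings, recovery of known
parameters) — it does not reproduce, and is never asserted against, the
numeric performance or shift percentages of any clinical dataset.

## Problem sizes

The default synthetic cohort is 100 patients × 3 exams (≈ 6,000 triplets);
the shift-property checks run on a 2,000-exam cohort (500 patients × 4
exams, ≈ 4,000 sides); parameter recovery uses 10,000 simulated triplets;
the conditional-distribution goodness-of-fit check uses 10,000 triplets
from 500 single-exam patients. These sizes give comfortable statistical
resolution for every asserted property while keeping a full run of the
suite fast on a single CPU.

## Known limitations

* Levels are computed only from complete (determinate) information; the
  package deliberately refuses to impute NT scores. Estimating missing
  scores is a natural extension that the model registry could support.
* The clinical model's 5/0/1 structure means its evaluation metrics are
  sensitive to how much probability mass a cohort puts on the
  intermediate sensory cells; comparisons with regression models should
  always be read together with the cohort's triplet distribution
  (`plot_triplet_frequencies()`).
* Contralateral (`ICSens`) models are fit and benchmarked but not used
  for level recalculation, which is ipsilateral by definition.
* The generator's independence assumptions (scores independent across
  segments given the lesion geometry) understate the spatial correlation
  of real exams; cross-validated metrics on synthetic cohorts are
  slightly optimistic for that reason.
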