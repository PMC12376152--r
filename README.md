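# vmscore

Virtual motor scores and motor level recalculation for ISNCSCI spinal cord
injury exams.

## The problem

The International Standards for Neurological Classification of Spinal Cord
Injury (ISNCSCI) grade light touch (LT) and pinprick (PP) sensation in 28
dermatomes (0–2 per side) and motor function in 10 key myotomes, C5–T1 and
L2–S1 (0–5 per side). The **motor level** is the most caudal segment graded
3 or better with all rostral segments intact — but most spinal segments
(C2–C4, T2–L1, S2–S4/5) have no clinically testable key muscle. There the
standards fall back on the *"motor follows sensory level"* rule: the motor
level is inferred from the sensory level.

One way to make that rule explicit is to assign every such segment a
**virtual motor score** predicted from the segment's own sensory scores,
turning motor level determination into the same rostral-to-caudal scan used
for the sensory level. `vmscore` implements this two-step analysis for
clinicians and methodologists working with ISNCSCI data:

1. **Predict** virtual motor scores from same-segment sensory scores with
   three model families over four sensory feature sets (ipsilateral LT,
   ipsilateral PP, both, or both sides' LT and PP):
   - the consensus **clinical model** (CLM): 5 if LT and PP are normal, 0
     if both absent, else 1;
   - **linear regression** (MLR), e.g. the published ipsilateral model
     `MS = 0.18 + 1.22·LT + 0.96·PP`;
   - **random forest regression** (RFR), characterized by feature
     importances.
   Because sensory inputs are integers, every model reduces to a lookup
   table (3, 9 or 81 rows); raw predictions are *mathematically rounded*
   (half-up, threshold 4.5) and clamped to 0–5.
2. **Recalculate** motor levels from virtual plus examined motor scores and
   quantify, over a cohort, how far the recalculated level deviates from
   the true (rule-based) motor level — in segments, positive = caudal. For
   any ipsilateral model that predicts a rounded 5 only for fully normal
   sensation, the deviation is provably 0 or +1.

Since clinical ISNCSCI exam databases are not freely redistributable, the
package also ships a seeded generator of synthetic cohorts with a
configurable lesion-band/severity mix and motor–sensory coupling, so the
whole pipeline (model fitting, grouped cross-validation, level
recalculation, shift statistics) runs end to end without any download.

## Worked example

```r
library(vmscore)

# the published ipsilateral LT+PP linear model as a lookup table
lookup_table(published_models()$MLR_ISens)
#>     ilt   ipp   raw rounded
#> 1     0     0  0.18       0
#> 2     0     1  1.14       1
#> 3     0     2  2.1        2
#> 4     1     0  1.4        1
#> 5     1     1  2.36       2
#> 6     1     2  3.32       3
#> 7     2     0  2.62       3
#> 8     2     1  3.58       4
#> 9     2     2  4.54       5
```

The raw column is the unclamped regression prediction; the rounded column
is what enters level determination. Only fully normal sensation (2,2)
reaches a rounded 5, so a chain of virtual 5s can never outrun the sensory
level.

```r
# a high cervical impairment: C3 light touch altered, C4 LT altered + PP absent
side <- side_scores(lt = c(C3 = 1, C4 = 1), pp = c(C4 = 0))
sensory_level(side)$level                                    # "C2"
true_motor_level(side)$level                                 # "C2"  (rule-based)
recalc_motor_level(side, published_models()$MLR_ISens)$level # "C3"  (one caudal)
```

The true motor level follows the sensory level to C2; the regression model
rounds the C3 prediction at (LT=1, PP=2) to 3, which lets the level run one
segment further — the only kind of disagreement an ipsilateral model can
produce.

```r
# cohort-scale validation on a synthetic 600-exam cohort
cohort <- generate_cohort(generator_config(n_patients = 200, seed = 7))
analyze_shift(cohort, published_models()$MLR_ISens)
#> <vms_shift> model: vms_linear_ISens
#>   included sides: 749 of 1200 (0 indeterminate)
#>   match: 51.54%  one caudal: 48.46%
#>   shift: 0.48 +/- 0.50 segments (median 0, IQR 1)

# fit and cross-validate a linear model on the cohort's segmental triplets
rows <- extract_triplets(cohort)
glance(cv_evaluate(rows, "MLR", "ISens", cv_config(seed = 7)))
#>   model feature_set r2_mean  r2_sd rmse_mean rmse_sd n_folds
#> 1 MLR   ISens         0.767 0.0258      1.09  0.0567      25
```

Only sides whose motor level was *determined by sensory function* enter the
shift statistics (detected by temporarily replacing all sensory scores with
normal scores and recomputing the level); every shift is 0 or +1 segments,
and replacing the regression model with the clinical model reproduces the
true level exactly. The match percentage itself depends on the cohort's
lesion mix — values on synthetic cohorts are not estimates of any clinical
cohort's values.

`autoplot()` methods visualize lookup tables and shift distributions;
`tidy()`/`glance()` return tibbles for models, cross-validation results and
shift analyses. A small CLI wraps the same functions
(`Rscript inst/cli/vmscore.R generate|train|predict|levels|shift|tables ...`).

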