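# iscee

Energy-expenditure estimation from multi-site wearable sensors for
ambulatory individuals with an incomplete spinal cord injury (iSCI), and the
translation of institutional physical-activity guidelines into daily step
goals for this population.

## The problem

Commercial activity trackers estimate energy expenditure (EE) from step or
activity counts calibrated on non-disabled gait. In ambulatory people with
an iSCI, step detection degrades at slow pathological gait, the energy cost
of walking is elevated and varies with impairment, and assistive devices add
further cost — so both the EE estimates and the familiar activity targets
("10,000 steps a day") mislead. `iscee` implements a dedicated pipeline for
this population:

1. **Preprocessing** — zero-phase 2nd-order Butterworth filters (0.25 Hz
   high-pass on acceleration, 0.2 Hz low-pass on barometric altitude),
   stream alignment by linear interpolation, segmentation into 60-s windows
   from minutes 4–8 of each activity (EE steady state), and gating of
   incomplete or non-steady windows.
2. **Feature bank** — 351 named features per window: per-site statistics of
   the acceleration magnitude `a_M`, gyroscope magnitude `w_M`, ankle
   sagittal angular velocity `w_Z` and altitude `H` (names like
   `PERC_95(w_Z_DA)` = 95th percentile at the dominant ankle), plus
   high-level features (gyroscope-based step detection, walked distance,
   stride-time variance, limb-use laterality, left/right cross-correlation,
   altitude change, activity counts), demographics and clinical scores.
3. **Activity-class gate** — a k-nearest-neighbour classifier (k = 10,
   squared-inverse-distance weighting, five published features) assigning
   each window to sedentary / low-intensity / high-intensity / walking.
4. **EE regression** — `EE = b0 + sum(bi * Fi)` fitted by minimising the sum
   of squared *relative* errors (closed form: weighted least squares with
   weights `1/y^2`), either directly or class-conditionally (one model per
   activity class, routed by true labels or by the gate). An ensemble of
   Levenberg–Marquardt-trained single-hidden-layer sigmoid networks
   (Nguyen–Widrow initialisation, early stopping, mean over 100 nets) is the
   alternative regressor.
5. **Resting EE** — Harris–Benedict, updated Harris–Benedict (default),
   Mifflin–St Jeor and Müller prediction equations.
6. **Evaluation** — MAE / mean signed error in % and kcal/day (averaged
   within subject first), Bland–Altman 95 % limits of agreement, paired
   equivalence testing (TOST, ±10 % zone), MET conversion
   (1 MET = 3.5 mL O₂·kg⁻¹·min⁻¹), leave-one-subject-out cross-validation
   throughout.
7. **Guideline translation** — daily step/minute goals from per-speed energy
   cost and cadence (e.g. "30 min of moderate activity", "300 kcal",
   "10,000 steps" → an iSCI-equivalent benchmark around 8,000 steps).

Because the clinical study data behind this design are confidential, the
package ships a seeded **synthetic cohort generator** (`sim_config()`,
`simulate_cohort()`): virtual subjects matching the published demographics,
8-site inertial/barometric signals with class-specific morphology,
ground-truth step events and MET-calibrated EE labels. Every pipeline stage
is tested against it.

## Worked example

```r
library(iscee)

cfg <- sim_config(n_subjects = 8, seed = 1)     # virtual cohort
fc  <- simulate_feature_cohort(cfg)             # windows -> feature table
ft  <- fc$features

print(loso_classify(ft))                        # activity-class gate
#> <confusion_report> accuracy 100.0% (n = 384)
#>
#>                  sedentary low_intensity high_intensity walking
#>   sedentary             96             0              0       0
#>   low_intensity          0            96              0       0
#>   high_intensity         0             0             96       0
#>   walking                0             0              0      96

res <- loso_ee(ft, "class_conditional", "mlr", "classifier")
print(error_metrics(res$ee_meas, res$ee_pred, res$subject_id))
#> <ee_eval> MAE 19.5 +- 5.5% (1042 +- 537 kcal/day), MSE -2.4 +- 17.4%
#>   max |err| 89.9% (7876 kcal/day), r = 0.929, rho = 0.956, n = 384 windows / 8 subjects
```

The leave-one-subject-out MAE of about 20 % on the synthetic cohort reflects
the generator's own 10 % label noise plus between-subject variability; the
direct (non-class-conditional) model on the same cohort is consistently
worse (29.8 % here), which is the pipeline's central design claim.

Guideline translation from the published per-speed profiles:

```r
subset(build_translation_table(), guideline == "300kcal_10000_steps",
       c(speed, goal_minutes, goal_steps))
#>        speed goal_minutes goal_steps
#>            1          173       9700
#>            2          134      10155
#>            3          107       9429
#>            4           64       6702
#>            5           71       8008
#>            6           56       6975
#>  average_all           92       8332
```

Walking 300 kcal off at typical speeds needs roughly 6,700–10,200 steps —
i.e. the "10,000 steps" recommendation translates to about 8,000 steps per
day for ambulatory individuals with an iSCI.

A thin command-line interface wraps the same functions
(`Rscript inst/cli/iscee.R simulate|extract-features|ree|classify|fit|predict|evaluate|recommend ...`).

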