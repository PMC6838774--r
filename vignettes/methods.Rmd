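---
title: "Estimating energy expenditure in ambulatory incomplete spinal cord injury: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating energy expenditure in ambulatory incomplete spinal cord injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscee)
```

## The estimation problem

For ambulatory individuals with an incomplete spinal cord injury (iSCI),
energy expenditure (EE) during daily activities cannot be read off
consumer-grade trackers: pathological gait breaks their step detection, and
the energy cost of movement is elevated and impairment-dependent. `iscee`
estimates per-minute EE (canonically expressed in kcal/day) from eight
body-worn inertial/barometric modules — both wrists, both ankles, both feet,
chest and hip — together with demographics, clinical scores and an estimate
of resting energy expenditure (REE).

The pipeline is: filter and window the raw signals, compute a named feature
bank, classify each one-minute window into one of four activity classes
(sedentary, low-intensity, high-intensity, walking), and apply a
class-specific regression to estimate EE. Evaluation is always
leave-one-subject-out (LOSO): the model scoring a subject has never seen
that subject's windows.

## Preprocessing

Acceleration is high-pass filtered (2nd-order Butterworth, 0.25 Hz) to
remove the gravity component before magnitudes are taken; altitude is
low-pass filtered (2nd-order, 0.2 Hz) to suppress barometric noise;
gyroscope channels are left unfiltered, since only the acceleration and
altitude filters are part of the protocol this package implements. All
filters are applied forward–backward (zero phase): the analysis is offline,
so the squared magnitude response costs nothing and features stay aligned
with the raw streams. The implementation pads reflectively with a pad
length sized from the slowest filter pole, so that the zero-initial-condition
transient decays inside the pad; a constant survives the high-pass at below
1e-6 and a linear altitude ramp passes the low-pass with sub-centimetre
error (both are asserted in the test suite).

Each activity contributes the four one-minute windows from minutes 4–8,
when EE has reached a steady state; the REE reference is the average of
minutes 14–18 of the resting measurement. Windows missing a sensor or an EE
label, or failing a steady-state screen, are dropped with an explicit
reason. The steady-state screen is a reproducible stand-in for visual
inspection: within-window coefficient of variation below 15 % and window
mean within 20 % of the neighbouring window's mean; both thresholds are
arguments.

## The feature bank

Feature names follow a `STAT(signal_site)` grammar — e.g. `PERC_95(w_Z_DA)`
is the 95th percentile of the sagittal-plane angular velocity at the
dominant ankle; dominance is resolved from handedness. Signals are the
acceleration magnitude `a_M` (high-pass filtered), gyroscope magnitude
`w_M`, ankle sagittal angular velocity `w_Z` and filtered altitude `H`.

The default bank has 351 features. The published per-site totals (36
statistical features for wrists, feet, chest and hip; 52 for ankles; 351
overall including high-level features, demographics and clinical scores)
fix the bank's size but not its exact composition, which is a package
choice: `a_M` carries 13 base statistics plus activity counts (AC), `w_M`
and `w_Z` the 13 base statistics, and `H` a reduced set (9 at non-ankle
sites, 12 at ankles) because extreme percentiles of a slowly varying
altitude duplicate its range. Quantiles interpolate linearly between order
statistics (R type 7); SD and variance use the n−1 denominator. Every
feature name used by the shipped model presets resolves in this bank, and
the resolver round-trips name → (statistic, signal, site) → name.

Definitions the protocol leaves open are fixed as follows and noted here
once:

* **Activity counts**: time integral of the rectified high-pass-filtered
  acceleration magnitude, in g·s — device-independent, linear in amplitude.
* **Laterality**: the symmetric ratio `(AC_dom − AC_nondom)/(AC_dom +
  AC_nondom)` in [−1, 1], computed for wrists, ankles, feet, and summed
  wrists vs summed ankles; 0 when both sides are inactive.
* **Step detection**: peaks of the 5 Hz-low-passed ankle `w_Z`, height at
  least `max(20 deg/s, 0.3 × window P95)`, 0.3 s refractory gap; each peak
  is one step of that leg. The thresholds are arguments; the defaults were
  validated against the simulator's ground-truth event lists (≥ 99 %
  sensitivity and positive predictive value at zero sensor noise).
* **Step length**: the static method, 0.415 × height (men) / 0.413 × height
  (women); configurable constants.
* **Cross-correlation**: maximum normalised cross-correlation of the
  mean-removed magnitudes over lags within ±1 s (computed by FFT with
  zero-padding, so all lags in the search window are exact linear
  correlations).
* Missing features are an explicit `NA` sentinel, never a silent zero;
  models refuse rows with missing selected features.

## Activity classification

The class gate is k-nearest-neighbour with k = 10 and squared-inverse
distance weighting on five features: `PERC_95(w_Z_DA)`, `IQR(w_Z_DA)`,
`PERC_99(w_M_Ch)`, `PERC_25(w_M_NDW)`, `SD(H_NDW)`. Because these mix
deg/s and metres, distances are Euclidean on features standardised with the
training fold's statistics (whether the original protocol standardised is
unstated; unstandardised distances would be dominated by the angular-rate
features, so standardisation is the default and a flag). Exact-match
neighbours (zero distance) decide by majority among themselves; ties break
deterministically in the fixed class order sedentary < low-intensity <
high-intensity < walking. The implementation is checked for exact agreement
with a brute-force kNN oracle on random instances up to 200 rows.

## EE regression

The linear model `EE = b0 + sum(bi * Fi)` is fitted by minimising the sum of
squared relative errors, `sum(((fit − y)/y)^2)`, matching the percentage
error criterion used for evaluation. Because each residual is scaled by its
own (positive, fixed) target, this objective is exactly a weighted least
squares problem with weights `1/y^2`, so the fit is closed-form and unique
whenever the weighted design has full rank; rank deficiency is an error
naming the collinear columns rather than a silent drop. The closed form is
verified against a derivative-free optimiser in the tests (relative
objective gap below 1e-6 on 50 random instances). Predictions are affine
evaluations with no clipping — negative estimates are reported as-is.

The model bundle comes in two architectures: *direct* (one regressor) and
*class-conditional* (one regressor per activity class, each trained only on
windows whose true class it serves, routed at prediction time either by the
true labels — the "perfect classification" upper bound — or by the fitted
gate). Feature sets per model are shipped as named presets; no feature
selection search is implemented, since the procedure that produced the
published sets is not described. An optional greedy forward selection could
be layered on top but is deliberately out of scope.

The neural-network alternative trains, per model, an ensemble of
single-hidden-layer sigmoid (logistic; tanh is a flag) networks on
standardised inputs and targets: Nguyen–Widrow initial weights,
Levenberg–Marquardt minimisation of the squared error on a fresh random
70/30 training/validation split, stopping at 500 epochs, when the error
gradient falls below 1e-6, or when validation error rises six times in a
row (best-validation weights are kept). The ensemble prediction is the mean
over members (default 100; configurable down to a handful for quick runs),
and a master seed fans out per-net seeds so results are bit-reproducible.
Hidden-layer sizes follow the presets: 6 units for the direct model, 3 for
the class models.

Resting EE enters every EE model as a feature but never the classifier. Five
prediction equations are configured as data (coefficients transcribed once
from their primary sources and locked by tests): Harris–Benedict, updated
Harris–Benedict (the default, selected in the source study by MAE),
Mifflin–St Jeor and Müller; Müller's MJ/day-native form converts at
239.006 kcal/MJ. The BMI-dependent Müller variant ships *unconfigured*: its
BMI-class coefficient table lives only in its primary source, which was not
available for transcription, so `estimate_ree(..., "mueller_bmi")` raises an
explicit not-configured error unless the caller supplies the table. The
corresponding column of the equation-comparison report therefore covers four
equations by default.

## Evaluation statistics

Percentage errors are `(pred − meas)/meas × 100`. The headline MAE and mean
signed error are computed within subject first, then averaged (mean ± SD)
across subjects — the convention behind summaries like "15.2 ± 6.3 %"; a
flag switches to per-window pooling. Bland–Altman agreement uses bias ±
1.96 × SD of the paired differences; the paired equivalence test is two
one-sided t-tests against ±10 % of the mean measured EE (both p < 0.05 ⇒
equivalent), falling back to a direct comparison when the differences are
degenerate. MET conversion uses 1 MET = 3.5 mL O₂·kg⁻¹·min⁻¹ and an energy
equivalent of oxygen of 4.86 kcal/L — the calorimeter software behind the
original labels does not publish its constant, so a mid-range RER-neutral
value is fixed and configurable.

## Guideline translation

The translation table derives daily step and minute goals from per-speed
walking profiles: cadence, average resting EE and average measured EE at
speeds of 1–6 km/h (plus a moderate-speed average at a nominal 4.3 km/h and
an all-speed average at 3.3 km/h). The printed per-30-minute energy cost is
carried as an input for the moderate speeds 3–6 km/h; for 1–2 km/h and the
average profiles it is derived as `(measured − REE)/1440 × 30`, the
unrounded quantity that reproduces the published minute goals exactly (their
displayed per-bout energies are rounded). One published cell is internally
inconsistent — the 6 km/h additional EE prints 7,694 kcal/day while measured
minus resting EE gives 7,964 — so `additional_daily_ee()` computes the
difference and the discrepant cell is excluded from validation. Rounding is
half-away-from-zero, applied once at output: minute goals round the exact
quotient `target/cost × 30`, and step goals multiply the *unrounded* minutes
by cadence before rounding, avoiding double rounding. Published minute cells
reproduce exactly; published step cells depend on unrounded cadences that
are not printed, and agree within 1 %.

## The synthetic cohort

The data behind the original models are confidential, so the generator
defines the study conditions the package is tested under: 30 subjects (2:1
male, age 54.1 ± 11.9 years in 27–72, weight 75.5 ± 16.2 kg in 44–106,
height 1.71 ± 0.09 m in 1.48–1.91, truncated normals), 12 activities in
four classes with class MET means from the published energy-cost figures
(rest 0.9 ± 0.2 through badminton 6.0 ± 1.8 and stair climbing 7.1 ± 1.7),
the published speed–cadence mapping (56/76/88/105/113/124 steps/min at
1–6 km/h), measured REE equal to the updated Harris–Benedict prediction
times `1 + N(0, 0.10)`, and EE labels equal to the MET draw converted with
the shared MET constants times `1 + N(0, 0.10)`. Where the sources state no
value (sensor white-noise levels, gait timing jitter of 0.02 s, the 3 m/min
stair climb rate, per-subject amplitude variability), values were chosen
once as field-plausible and are config fields.

Signal morphology is deliberately simple — windowed sinusoids, Gaussian
pulse trains for steps, impacts, white noise — with class-specific
structure: walking produces anti-phase ankle pulse trains at the prescribed
cadence with arm-swing and chest bounce; the low-intensity class produces
*intermittent* (≈30 % duty cycle) upper-limb movement while the
high-intensity class moves continuously, so the low/high distinction is
structural rather than amplitude-only; stair climbing adds the altitude
ramp. All amplitudes scale with the drawn MET through class-specific gains,
which makes EE recoverable from the signals *and* makes a single global
linear model systematically misfit across classes — the property behind the
class-conditional ≤ routed ≤ direct MAE ordering that the acceptance suite
checks across 20 seeds.

What passing these tests shows — and does not show. The simulator
establishes that the pipeline recovers what it is built to recover:
injected steps, class structure, EE–feature relationships, and the
published arithmetic. It does not establish clinical accuracy on real iSCI
gait, which is more variable, less periodic, and contaminated by artifacts
the generator does not emulate (clock drift, sensor saturation, soft-tissue
motion); headline accuracies on the synthetic cohort are therefore not
comparable to values measured on patients.

## Numerical choices and problem sizes

* Analysis sampling rate 50 Hz (device-native recordings at 200 Hz are
  aligned and downsampled by linear interpolation); the simulator generates
  at the analysis rate directly.
* Windows are half-open intervals `[t0, t0 + 60)` aligned to activity-start
  minutes; no sample belongs to two windows.
* The test and acceptance runs size their simulations to single-CPU
  minutes: the LOSO classification check uses the full 30-subject cohort
  once; the MAE-ordering property uses 8-subject cohorts over 20 seeds
  (384 windows per seed, which keeps every class model comfortably
  overdetermined while leaving subject-level covariates identifiable in
  each leave-one-subject-out fold).
* Serialised models are JSON documents at full floating-point precision, so
  a written-and-reloaded model predicts identically.

## Known limitations

* The BMI-dependent Müller REE equation is a stub until its coefficient
  table is supplied.
* The ANN ensemble at its full published size (100 nets per model and fold)
  is computationally heavy in pure R; the default test configurations use
  smaller ensembles, which the seed policy keeps reproducible.
* The kNN gate stores its full training matrix (as the method requires);
  serialised gates grow linearly with the cohort.
* Steady-state gating approximates a visual screen; with real calorimetry
  its thresholds should be re-examined against expert labels.
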