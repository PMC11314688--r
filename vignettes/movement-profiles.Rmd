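---
title: "From wrist acceleration to 24-h movement profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From wrist acceleration to 24-h movement profiles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

wristmx implements the full computation chain used in wrist-accelerometry
studies of clinical cohorts — here, adults with type 2 diabetes with and
without active diabetic foot ulcers (DFU), where offloading treatment is
expected to depress both the volume and, especially, the *sustained*
intensity of daily activity. The chain runs from raw triaxial signal to
covariate-adjusted group contrasts:

1. auto-calibration of the raw signal to local gravity;
2. ENMO (Euclidean Norm Minus One, negatives truncated to zero) averaged
   over 5-s epochs, in mg;
3. non-wear detection and same-clock-time imputation;
4. wear-validity screening (the study inclusion rules);
5. nightly sleep-period-window detection from the wrist z-angle;
6. per-day movement metrics and their across-day average;
7. per-outcome GLMs with estimated marginal means for the group contrast.

Because the cohort data behind such studies are not openly available, the
package ships a synthetic-cohort generator that writes both the signal and
its ground truth from one schedule, so every stage can be validated by
recovery rather than by comparison to an inaccessible dataset.

## The movement metrics

**Average acceleration** is the mean of all 17,280 five-second ENMO epochs
of a calendar day (midnight to midnight): a volume proxy in mg. A 1-mg
contrast is the commonly used minimum clinically important difference.

**Intensity gradient.** Time accumulated in 25-mg intensity bins spanning
0–4000 mg falls away with intensity; the OLS slope of log(bin minutes) on
log(bin mid-intensity) over occupied bins summarises the whole intensity
distribution in one (always negative) number. The binning (25 mg, 0–4000,
natural logs, empty bins dropped) follows the established convention for
this metric; days with fewer than two occupied bins return a flagged
undefined result rather than a number. Construction-based tests plant
power-law days with exponents −1.5, −2 and −3 and require recovery within
±0.1.

**Category times.** Thresholds are read strictly: an epoch below 40 mg is
inactive, a 1-min interval whose mean exceeds 100 mg is MVPA
(moderate-to-vigorous physical activity), everything between is light; an
epoch at exactly 40 mg is light and a minute at exactly 100 mg is not
MVPA. MVPA is determined first on fully waking 1-min re-epoched means;
the remaining waking 5-s epochs are then split at 40 mg. This ordering
makes inactive + light + MVPA + sleep-window time an exact partition of
the 1440-min day (the conservation property the test suite asserts to
±1 min); counting the categories independently on overlapping time bases
would double-count epochs inside MVPA minutes.

**Inactivity bouts** are maximal runs of consecutive waking epochs
strictly below 40 mg; only runs strictly longer than 30 min count, with
no interruption tolerance — a single 5-s epoch at or above threshold
splits the run.

**MX metrics.** For each duration X ∈ {5, 10, 30, 60, 120} min:

* `MX_ACC` — the acceleration above which the most active X minutes of
  the day are *accumulated*: the (12·X)-th largest epoch value.
* `MX_CONT` — the acceleration exceeded for at least 75% of the single
  most active *continuous* X-min window: the maximum over all contiguous
  windows (stride one epoch, no wrap across midnight) of the
  within-window lower quartile.

The 25th percentile is the lower empirical order statistic at
⌈0.25·n⌉ with no interpolation, so results match a brute-force
sort oracle bit-for-bit. The defining sentence of `MX_CONT` ("75% of the
window above the value") is realized directly as the max-over-windows
quantile; the plausible alternative — the lower quartile of the window
with maximal *mean* — is also implemented and selectable
(`mx_cont_method = "best_window_quantile"`), because the two readings can
differ and the defining text does not force a unique operationalisation.
The default dominates the alternative, and `MX_ACC ≥ MX_CONT` holds for
every duration on every day by construction of the order statistics; both
facts are asserted empirically across thousands of random days. The
rolling order statistic is computed in C++ (a two-multiset sliding
window), keeping a full day × five durations under 0.1 s.

## Calibration, non-wear, inclusion

**Auto-calibration** looks for still 10-s windows (all three axis SDs
below 13 mg), then refines per-axis offset and gain by iteratively
reweighted least squares so still-window magnitudes approach 1 g; the
calibrated signal is `(raw + offset) * gain`. Iterations stop when the
largest parameter update falls below 1e-5 g (up to 1000 iterations — the
update sequence contracts geometrically but slowly, so a loose iteration
cap is the cheap, safe choice). If still windows are too few (< 10) or
span too narrow an orientation range (< 0.3 g per axis), the six
parameters are not identifiable and the identity transform is returned,
flagged unconverged; the same applies if the fit would *increase* the
still-point error, which guarantees the post-error never exceeds the
pre-error. The post-calibration error is the mean absolute deviation of
calibrated still magnitudes from 1 g, in mg.

**Non-wear** is flagged per 15-min block using a 60-min centred window:
at least two of three axes with SD < 13 mg and range < 50 mg. Flagged
runs are then extended outward over adjacent blocks that are quiet on
their own 15-min statistics; without this refinement a 90-min gap would
only ever have its central 30 min flagged (the centred window of an edge
block always overlaps worn signal), and planted-gap recovery would be
structurally capped near a third. For epoch-only input with no per-axis
signal, the same block machinery runs on the ENMO series with near-zero
thresholds (SD < 1 mg, range < 5 mg): an unworn device yields an
essentially constant ENMO while even motionless sleep retains a few mg of
noise. The surrogate is recorded in the result and announced in the log.

**Imputation** replaces each non-wear epoch by the mean of worn epochs in
the same 5-s time-of-day slot on the participant's other days; slots worn
on no day stay unimputed, which then fails the slot-coverage rule.
Imputed epochs keep a distinct flag, so wear statistics are always
computed on pre-imputation wear.

**Inclusion** requires all of: post-calibration error ≤ 10 mg; ≥ 3
calendar days with strictly more than 16 h of wear; every one of the 96
15-min clock slots worn on at least one day. The first violated rule (in
that order) is reported as the exclusion reason. Valid wear is evaluated
on calendar days because every reported metric is a midnight-to-midnight
quantity.

## Sleep

The z-angle, `atan(z / sqrt(x^2 + y^2))·180/π` averaged per 5-s epoch, is
insensitive to the azimuthal rotation of the wrist and tracks posture.
Per noon-to-noon night, 5-min rolling medians of absolute successive
angle differences are thresholded at 15× their 10th percentile, capped
into [0.1, 5]°; the upper cap matches the fixed 5° constant adopted by
later versions of the angle-based detection family, and matters on nights
where long quiet sleep drags the 10th percentile (and hence 15× it) above
any useful level. Runs below threshold lasting ≥ 30 min are candidate
rest blocks, candidates separated by < 60 min merge, and the longest
merged block is the night's sleep period window. Sustained-inactivity
runs (≥ 5 min below threshold) inside the window are labelled sleep;
outside, daytime sustained inactivity; runs straddling the boundary split
at it.

Sleep duration is the labelled-sleep time inside the window; efficiency
is duration over window length (per night, then averaged). The sleep
midpoint is the *circular* mean of nightly window midpoints — clock times
near midnight wrap, and an arithmetic mean of 23:30 and 00:30 would be
noon. Midpoint variability is the SD of nightly midpoints after
unwrapping about the circular mean, in min/day; a whole-cohort clock
shift moves the midpoint and leaves the SD untouched, which the tests
assert. Nights are noon-to-noon while waking metrics stay
midnight-to-midnight, with windows intersected per calendar day for
category accounting, because real sleep windows cross midnight.

For ENMO-only input the same detection machinery runs on the ENMO series
itself (cap band 1–10 mg) and all sleep outputs are marked approximate;
orientation is simply not recoverable without axes, and tests hold the
surrogate to hour-level, not minute-level, accuracy.

## Group comparison

Each outcome is regressed on group plus seven covariates: age, sex, BMI,
ethnicity, cardiovascular disease, diabetes duration and accelerometer
wear time (mean daily worn hours before imputation, expressed in days).
Rows with missing modelled values are dropped and counted. A
Gaussian-identity GLM is always fitted; when every outcome value is
positive a gamma-log GLM is fitted too, and the family with the lower
AIC is kept — the positivity guard exists because the gamma likelihood is
undefined otherwise (the intensity gradient, always negative, is a
routine example).

Estimated marginal means are computed with **emmeans**: continuous
covariates at their sample means, categorical covariates averaged over
the observed sample distribution (population-averaged,
`weights = "proportional"`; balanced `"equal"` weights are a switch,
since either convention is defensible and published tables rarely say
which was used). CIs are formed on the link scale and back-transformed;
the p-value is the Wald test of the group contrast. With group as the
only predictor the marginal means collapse to the raw group means, a
reduction the tests check to 1e-8.

The **percent difference** between groups is the symmetric form
`100·(a − b)/((a + b)/2)`. This choice is forced by arithmetic: applied
to the published adjusted group means bundled in
`dfu_reference_means()` it reproduces the published percent-difference
column at one decimal for nine of ten MX rows, which the plain relative
difference `100·(a − b)/a` does not. The
one exception (M120_ACC, printed 25.5 vs recomputed 25.7) is consistent
with the published column having been computed from unrounded means, so
the worked-example checks exclude it and nothing is forced beyond 1 d.p.

## The synthetic cohort

A participant is a daily schedule: a nightly sleep window (default onset
23:00, 465 min, efficiency 0.86), planted activity bouts at fixed clock
times, optional planted non-wear gaps, and filler wake time allocated to
intensity levels (defaults: 770 min/day near 15 mg, 185 min/day near
72 mg, plus two 10-min bouts at 140 and 250 mg). Defaults were chosen
once so that the non-ulcer preset lands near the published group
magnitudes — volume ≈ 22 mg, light ≈ 180 min, MVPA ≈ 20 min, sleep
≈ 400 min at 86% efficiency — and the ulcer effect (intensity × 0.78,
bout duration × 0.5) lands near 17 mg, i.e. a ≈ 5 mg adjusted volume
contrast. Wake noise is Gaussian truncated at zero (ENMO is
non-negative); sleep is generated as gravity on a stable per-night
orientation with ~1° elevation jitter and larger azimuth drift (so the
z-angle algorithm has a realistic target while still sleep does not
masquerade as non-wear on the raw axes); non-wear is an exactly constant
signal. In-window arousals are consolidated 10–20-min episodes spaced at
least ~30 min apart — fragmented sleep with sub-30-min quiet runs is
atypical and would defeat any candidate-block detector, ours included.
Inactive filler is laid down in ~40-min blocks so prolonged sedentary
bouts exist, as they do in this population.

Raw mode expands each epoch into constant samples of magnitude
1 + ENMO/1000 on the epoch's orientation, then plants per-axis
miscalibration by inverting the calibration model; epoch and raw modes
consume the RNG in the same order, so the same seed yields bit-identical
epoch series either way — the raw→epoch consistency the tests assert. A
separate still-posture simulator (random orientations held for a minute
each) provides the orientation diversity that calibration recovery needs.

What the generator does **not** emulate: bursty free-living intensity
fluctuation within activities (bouts are constant-intensity, so the
continuous MX metrics of synthetic days run higher, relative to
accumulated MX, than in real cohorts), naps outside the main window,
posture-change artefacts, device temperature effects, and non-wear that
coincides with the sleep window. Passing recovery tests therefore
demonstrates algorithmic correctness on signals with known truth, not
population realism of every metric's absolute level.

A second, lighter simulator (`simulate_trial_outcomes()`) draws the seven
covariates from per-group presets (groups genuinely confounded: the
ulcer preset is younger, more male, longer diabetes duration) and an
outcome from a GLM with a known adjusted contrast (default 22 vs 17 mg,
i.e. 5.0 mg). It validates the statistical stage at scale — estimate
within ±0.5 mg at n = 500/group, 95% CI coverage inside 93–97% over 200
replicates, AIC recovering the generating family in ≥ 80% — without
paying for signal generation.

## Numerical choices and degenerate inputs

* Epoch intervals are half-open `[start, start + 5 s)`, 0-based within
  the day; all slot arithmetic is integer.
* Negative per-sample ENMO is truncated before epoch averaging, per the
  metric's definition.
* MX windows never wrap midnight; metrics are per-calendar-day.
* Zero-magnitude samples make the z-angle undefined (NA) for that epoch.
* A day whose epochs fall in fewer than two intensity bins has no
  gradient (flagged, not NaN).
* `symmetric_percent_difference` is undefined when the means sum to
  zero or less; the comparison table reports NA there.
* Problem sizes in the validation suites — 1,000 shortened days plus
  hundreds of full days for the MX oracles, 100 nights for sleep
  recovery, 200 replicates at n = 500/group for the statistical suite —
  were fixed once as the package's standing test conditions.

## Known limitations

* The GENEActiv `.bin` container is out of scope; input is long-format
  CSV (or any source the user parses into `triaxial_recording()`).
* Non-wear detection carries no temperature channel and no
  idle-sleep-mode handling.
* Sleep outputs from ENMO-only input are approximate by construction.
* No nap detection outside the main window, no sleep staging, no bouted
  MVPA variants, no MET translation.
* p-values are unadjusted for multiplicity, matching the analysis style
  the pipeline reproduces.
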