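# wristmx

Wrist-accelerometry movement profiling for clinical two-group studies:
from raw triaxial acceleration to calibrated 5-s ENMO epochs, 24-hour
movement metrics, sleep-window statistics, and covariate-adjusted group
contrasts. The package was built around the analysis design used to
compare people with type 2 diabetes with and without active diabetic
foot ulcers (DFU) — a population whose offloading treatment is expected
to suppress *sustained* activity intensity more than accumulated
activity — but every stage is generic wrist-accelerometry methodology.

## What it computes

For each participant-day (midnight to midnight, 17,280 five-second
epochs of ENMO in mg, where ENMO = max(0, ‖(x,y,z)‖ − 1 g)):

| Metric | Definition |
|---|---|
| Average acceleration | mean ENMO over the 24-h day (volume proxy, mg) |
| Intensity gradient | slope of log(minutes in 25-mg bin) vs log(bin mid-intensity) |
| Inactivity (total / bouts) | waking time < 40 mg; runs > 30 min |
| Light / MVPA | waking time 40–100 mg; 1-min intervals with mean > 100 mg |
| MX_ACC (X ∈ 5…120 min) | (12·X)-th largest epoch: intensity of the most active accumulated X min |
| MX_CONT | max over contiguous X-min windows of the within-window lower quartile: the intensity exceeded for ≥ 75% of the most active continuous X min |
| Sleep duration / efficiency / midpoint (SD) | from the nightly sleep-period window detected via sustained low variation of the wrist z-angle |

Upstream, the package auto-calibrates the raw signal to local gravity
(still-window sphere fit; post-error in mg), detects and imputes
non-wear, and applies the standard inclusion rules (calibration error
≤ 10 mg; ≥ 3 days with > 16 h wear; all 96 15-min clock slots covered).
Downstream, each outcome is fitted with a Gaussian-identity GLM (and a
gamma-log GLM when positive, the better AIC winning) and summarised as
estimated marginal means adjusted for age, sex, BMI, ethnicity,
cardiovascular disease, diabetes duration and wear time, plus the
symmetric percent difference `100·(a − b) / ((a + b)/2)`.

Because participant-level data for such cohorts are typically not
shareable, a synthetic-cohort generator writes signal and ground truth
from one schedule (sleep windows, arousals, activity bouts, non-wear
gaps, calibration distortion), so the whole pipeline is testable by
recovery.

## Worked example

```r
library(wristmx)

co  <- generate_cohort(cohort_spec(n_per_group = c(nonDFU = 6, DFU = 6),
                                   days = 7, seed = 42))
cfg <- pipeline_config(model = list(weights = "proportional",
                                    family = "auto",
                                    covariates = c("age", "sex", "bmi")))
res <- run_pipeline(co$data, co$covariates, cfg)
res$results[, c("outcome", "mean1", "mean2", "p_value",
                "percent_difference")]
```

selected rows of the printed comparison table (group 1 = nonDFU,
group 2 = DFU; means with 95% CI on the response scale):

```
            outcome  mean1 lower1 upper1  mean2 lower2 upper2 p_value percent_difference
   avg_acceleration  21.67  17.11  26.23  15.08  10.52  19.64 0.10271            35.8457
               mvpa  20.25  17.15  23.35   7.87   4.77  10.97 0.00126            88.0612
             M5_ACC 247.78 188.68 306.88 162.40 103.30 221.50 0.10257            41.6295
     sleep_duration 398.33 396.48 400.18 398.18 396.33 400.03 0.91970             0.0374
   sleep_efficiency  85.59  85.20  85.98  85.56  85.17  85.95 0.92567             0.0338
```

Reading it: the simulated ulcer group preset plants lower wake intensity
and half-length bouts; the pipeline recovers a volume contrast of
~6.6 mg against generator truth volumes of 20.5 vs 16.2 mg (n = 12 is a
demo size, hence the wide CIs), a large MVPA deficit, and — by design —
untouched sleep. On published adjusted means the percent-difference
operation reproduces the reported values, e.g.

```r
symmetric_percent_difference(81.6, 53.4)   # M5_CONT means -> 41.77778
```

`run_pipeline(..., out_dir = )` also writes `metrics.csv`,
`results.csv`, `exclusions.csv`, `sleep.csv`, a formatted text report
and a run log (seed, config hash, inclusion verdicts). A thin CLI over
the same functions lives at `inst/cli/wristmx.R` with subcommands
`simulate`, `ingest`, `metrics`, `sleep`, `compare`, `run`, `report`.

## Package layout

- `R/simulate.R`, `R/schedule.R` — synthetic cohort with ground truth
- `R/calibration.R`, `R/ingest.R` — calibration, ENMO epochs, non-wear,
  imputation, inclusion rules
- `R/metrics.R`, `src/rolling_stat.cpp` — daily metrics and the MX
  rolling-quantile kernel
- `R/sleep.R` — z-angle, sleep-window detection, sleep summaries
- `R/compare.R` — GLM + estimated marginal means + percent differences
- `R/pipeline.R` — configuration (YAML round-trip) and orchestration
- `vignettes/movement-profiles.Rmd` — methods, design decisions and
  limitations in full
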