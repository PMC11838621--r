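# gaitmob

Digital phenotyping of physical function from smartphones: an R package and
analysis workflow that turns raw, duty-cycled accelerometer and GPS streams
into six daily gait and mobility measures, filters them to valid days,
aligns them with patient-reported outcome measures (PROMs), and fits
longitudinal mixed-effects association models — the analysis pattern used to
monitor functional status in advanced cancer cohorts from patients' own
phones.

**Who it is for.** Biostatisticians and mHealth researchers working with
Beiwe-style raw sensor exports (accelerometer sampled ~10 Hz in 10 s-on /
20 s-off cycles; GPS in 1 min-on / 10 min-off cycles) who need daily
behavioural measures and their association with instruments such as ECOG
performance status, EQ-5D-5L, and PROMIS Physical Function 6b. Because
patient-level sensor data cannot be shared, the package includes a fully
specified synthetic-cohort generator with planted ground truth, so every
stage is testable and the whole analysis is reproducible without any
download.

## The measures and the model

Per participant-day, from the accelerometer (via the vector magnitude
`vm = sqrt(x² + y² + z²)`, in g):

- **step count** — sum of one-second step frequencies over seconds
  classified as walking (dominant spectral frequency in [1.4, 2.3] steps/s
  with amplitude ≥ 0.1 g), scaled by the duty cycle: observed steps ×
  (10 + 20)/10 = 3;
- **gait cadence** — 60 × mean one-second step frequency (steps/min);
- **stride acceleration** — mean |vm − 1| over strides (peak *i* to peak
  *i+2*) rescaled to a common template; `2A/π` for a sinusoid of
  amplitude A.

From GPS, after projecting fixes to a local plane, segmenting them into
pauses (≥ 5 min within 50 m) and straight flights (split at heading changes
> 30°), and bridging duty-cycle gaps by a displacement rule that preserves
time conservation:

- **home time** — hours in pauses within 50 m of home, the location with
  the most night-time (20:00–08:00) pause time;
- **distance traveled** — sum of flight lengths (km);
- **significant locations** — clusters of pauses ≥ 15 min, ≥ 50 m apart,
  visited that day.

A day is **valid** with ≥ 960 minutes (16 h) of collected data; analyses
use valid days only. Measures are averaged within ±10 days of each
completed survey and modelled as

```
measure_it = β0 + β · PROM_it + u0_i + u1_i · month_it + ε_it
```

— a linear mixed model (REML, lme4) with participant random intercepts and
random slopes on months since baseline; Wald 95% CIs. Categorical PROMs
(ECOG, EQ-5D-5L items) use the best health state as reference; PROMIS PF 6b
enters as a T-score. Companion models estimate baseline + monthly trend,
and smartphone-use associations with data quality.

See `vignettes/gaitmob-methods.Rmd` for assumptions, parameter defaults,
and design decisions.

## Worked example

The `analysis/` scripts run the full workflow on a synthetic 8-participant,
28-day cohort (raw CSVs under `scratch/`, summary tables under `results/`):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_extract_daily_measures.R
Rscript analysis/03_align_and_adherence.R
Rscript analysis/04_fit_models.R
Rscript analysis/05_model_calibration.R
```

Stage 2 prints the recovery of the planted per-day truth:

```
extracted 220 participant-days (167 valid) -> results/daily.csv
recovery on valid days: steps MAPE 1.27%, cadence MAE 0.23 steps/min,
stride MAE 0.0012 g, home MAE 0.000 h, distance MAPE 0.00%, locations exact 100%
```

i.e. step counts land within ~1% of the planted truth, cadence within a
quarter step/min, and the GPS schedule (home time, distance, locations) is
recovered essentially exactly. Stage 4 then fits the association models:

```
steps ~ PROMIS T: +80.3 steps/day per T-point [67.9, 92.7], p = 5.1e-37
```

recovering the planted link of +72.6 steps/day per PROMIS T-point within
its confidence interval at this small cohort size. Stage 5 calibrates the
estimators at the study scale (85 participants × 4 surveys, 200 replicates
per scenario): relative bias below ~2%, 95% CI coverage 0.905–0.975, and
type-I error 0.06 under a null link (see `results/calibration.csv`).

Interactive use mirrors the scripts:

```r
library(gaitmob)
cfg <- cohort_config(n_participants = 8, study_days = 28,
                     survey_days = c(0, 7, 14, 21), window_days = 3)
res <- run_pipeline(cfg, out = "scratch/run", seed = 1)
tidy_fit(res$fits$association[["steps_adjusted~promis_t"]])
```

## Layout

```
R/                 package code: sensor IO, gait and mobility metrics,
                   valid-day alignment, PROM scoring, mixed models,
                   synthetic cohort, pipeline
analysis/          numbered workflow drivers (simulate -> extract -> align
                   -> model -> calibrate)
scripts/           acceptance.R
tests/testthat/    unit, property and acceptance tests
vignettes/         methods vignette
inst/extdata/      synthetic PROMIS PF 6b raw-to-T table (replaceable)
```
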