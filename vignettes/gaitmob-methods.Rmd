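---
title: "Smartphone gait and mobility measures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smartphone gait and mobility measures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gaitmob turns raw, duty-cycled smartphone sensor streams into six daily
digital measures of physical activity and mobility, aligns them with
patient-reported outcome measures (PROMs), and fits longitudinal
mixed-effects association models. This vignette documents the models and
procedures, the parameters that matter, the synthetic cohort that stands in
for patient data, and the design choices made where the problem was
genuinely open.

## The measurement problem

Smartphones sample sensors intermittently to preserve battery: the
accelerometer records roughly 10 seconds of tri-axial data at 10 Hz followed
by a 20-second pause; GPS records for 1 minute followed by a 10-minute
pause. Any daily summary must therefore (i) work per *on-bout*, (ii) scale
observed activity up to the full day, and (iii) bridge the gaps in the
location record before durations and distances are accumulated.

Six measures are derived per participant-day:

| measure | sensor | definition |
|---|---|---|
| step count | accelerometer | sum of one-second step frequencies over walking seconds, scaled by the duty cycle |
| gait cadence | accelerometer | mean one-second step frequency over walking seconds, steps/min |
| stride acceleration | accelerometer | mean absolute deviation of vector magnitude from 1 g over rescaled strides |
| home time | GPS | hours in pauses within 50 m of the home location |
| distance traveled | GPS | sum of straight-flight lengths, km |
| significant locations | GPS | clusters of pauses ≥ 15 min, ≥ 50 m apart, visited that day |

## Gait measures

All gait processing operates on the orientation-invariant vector magnitude
`vm = sqrt(x^2 + y^2 + z^2)` (≈ 1 g at rest), so a phone loose in a pocket
or bag contributes the same signal regardless of how it is held.

**Walking classification.** Within each on-bout, `vm` is linearly resampled
to a uniform grid at the nominal rate (phone timestamps jitter), demeaned,
and Fourier-transformed with zero padding to a frequency resolution well
below 0.1 Hz. Every whole second covered by the bout is labelled *walking*
iff the dominant spectral frequency lies in the cadence band
(`walk_f_min = 1.4` to `walk_f_max = 2.3` steps/s, the typical adult walking
range) and its amplitude reaches `min_peak_amp = 0.1` g. Walking seconds
carry the dominant frequency as their one-second step frequency. Bouts
shorter than 2 s cannot support the spectral estimate and are labelled
non-walking. All three thresholds are configurable via `gait_params()`.

**Step count.** Observed steps are the sum of step frequencies over walking
seconds. Because the sensor observes only `on / (on + off)` of the time, the
observed sum is multiplied by `(on + off) / on` — exactly 3 for the default
10 s / 20 s scheme — and rounded to an integer. This proportional adjustment
assumes walking is not synchronised with the duty cycle, which holds for any
realistic bout length.

**Cadence** is 60 times the mean step frequency over walking seconds. An
open question was whether to average per-second frequencies or per-minute
step totals; we average per-second frequencies, which is equivalent under
within-day stationarity of gait and robust to partial minutes.

**Stride acceleration.** Step peaks are local maxima of the smoothed `vm`
(centered moving average, width = rate/4 samples; minimum spacing
`1 / walk_f_max` s). A stride spans peak *i* to peak *i+2* (two consecutive
steps). Each stride segment is rescaled to a 100-sample template and scored
as the mean of `|vm − 1|` — the absolute deviation from the gravity
baseline; the daily value is the mean over strides. For a sinusoidal `vm`
of amplitude A the score is `2A/π`, which gives an analytic oracle used in
the tests. Two numerical choices matter: deviations are measured from 1 g
(not from the segment mean), because published population values
(~0.05–0.10 g) are consistent with a gravity-referenced reading; and
template resampling uses spline interpolation, because linear chords
systematically under-integrate `|vm − 1|` near peaks at 10 Hz sampling
(about −10% for a 1.8 Hz tone).

## Mobility measures

**Projection.** Fixes are projected onto a local plane by an
equirectangular map about the trace's median latitude/longitude. At daily
travel scales the distortion relative to geodesic distances is far below
the GPS noise floor (< 0.1% at city scale), and planar geometry keeps pause
detection and clustering simple.

**Flights and pauses.** A greedy scan finds maximal runs of fixes that stay
within `pause_radius_m = 50` of the run's running centroid; runs spanning at
least `min_pause_s = 300` become Pauses. Between pauses, consecutive fixes
form straight Flights, split whenever the heading turns by more than
`max_heading_change_deg = 30` — the operationalisation of travel "without a
directional change". Pause *detection* is deliberately finer (5 min) than
the 15-min *significant-location* filter: short stops must anchor the
trajectory even when they do not count as visited locations.

**Gap imputation.** Duty cycling leaves most of each hour unobserved. For
each gap the displacement between the flanking observed positions decides
the fill: under 50 m, a Pause at the midpoint; otherwise a single
constant-speed straight Flight. Leading/trailing gaps are filled as Pauses
at the nearest observed position. This rule deliberately replaces a
Gaussian-process trajectory imputation with the simplest fill that
preserves the *time conservation* contract — after imputation, pause plus
flight durations cover every second of every day — and it is exact on
piecewise flight/pause ground truth.

**Significant locations.** Pauses of at least 900 s (boundary inclusive)
are clustered greedily in descending-duration order; a candidate joins the
first cluster whose centroid lies within 50 m (duration-weighted centroid
update), else founds a new cluster. The day's count is the number of
clusters with at least one qualifying pause that day; home is included (no
exclusion is stated in the field definitions we follow).

**Home.** Among clusters, home is the one with the greatest pooled pause
time inside nightly 20:00–08:00 local windows. Daily home time then
accumulates over the whole 24-h day, not only the night window: a night-only
reading could never exceed 12 h, while observed cohort values are ~15 h.

## Valid days, alignment, and adherence

A minute counts as *covered* when at least one raw sample from either
sensor falls in it — the most permissive deterministic reading of
"collected data". A day is *valid* with ≥ 960 covered minutes (16 h),
boundary inclusive; all analyses use valid days only. Daily measures are
averaged over valid days within ±`window_days` of each completed survey
(closed interval; default 10 days, anchored on the completion date).
Adherence is summarised per participant as collected days / expected days
and valid days / expected days. The smartphone-use analysis averages each
measure over valid days in study days 0–13.

## Longitudinal models

Associations are estimated with linear mixed-effects models fit by REML
(lme4), with the digital measure as outcome and the survey response as
predictor:

```
outcome_it = b0 + b * PROM_it + u0_i + u1_i * month_it + e_it
```

with participant random intercepts `u0` and random slopes `u1` on months
since baseline (study day / 30.44). Categorical predictors (ECOG PS,
EQ-5D-5L items) use the best health state as reference (ECOG 0, item
level 1); PROMIS PF 6b T-scores enter linearly. Trend models replace the
PROM with a fixed month term, reporting baseline level and monthly change.
Wald 95% CIs and Wald z p-values are reported (α = 0.05 per model, no
multiplicity adjustment — each model is reported, not selected). No fixed
time term is included alongside a PROM predictor: the models are
deliberately unadjusted bivariate descriptions, and the random slopes
absorb smooth participant-level drift.

Singular random-slope fits fall back to a random intercept only, then — for
one-row-per-participant designs such as the smartphone-use models — to
ordinary least squares; the `model_type` field of every fit records which
model produced the estimates. A predictor with no variation is reported as
non-estimable rather than an error.

PROMIS PF 6b raw scores (6–30) are converted to T-scores by sum-score table
lookup. The official conversion table is licensed separately, so the
package ships a clearly labelled synthetic, strictly monotone stand-in
(linear map onto T 22.0–60.4) that can be replaced via the `table` argument
of `promis_raw_to_t()`; every property the pipeline relies on (monotonicity,
range validation) holds for any valid table.

## The synthetic cohort

Patient-level sensor data cannot be redistributed, so the generator is a
first-class, tested module. Defaults emulate the target study: 85
participants, 180 days, surveys at days 0/30/90/180, the duty cycles above,
PROMIS T ≈ N(44.4, 8) per wave, and a baseline ECOG mix of roughly
32/54/9/5% across levels 0–4.

Day-level measure means follow the same linear structure the models assume:

```
measure_id = intercept + link * T_i,wave(d) + trend * month + u0_i + u1_i * month + noise
```

with the wave taken as the nearest completed survey. Intercepts and PROMIS
links default to published cohort-scale coefficients (e.g. +72.6 steps/day
per T-point against a −964.4 intercept, implying ≈ 2,259 steps/day at the
mean T-score; cadence ≈ 105 steps/min; home time ≈ 15 h; ~4 significant
locations). ECOG step offsets (0, −500, −1100, −1837, −1837) are available
in the configuration but default to zero so the steps scale is governed by
one link at a time; categorical-offset recovery is studied with the
aligned-level simulator, planting one predictor per scenario.

Targets are rendered into physically realisable schedules, and the truth
table records the *achieved* values so recovery can be checked exactly:

- **Gait**: walking minutes = step target / cadence; cadence is kept inside
  the detector band (87–135 steps/min) and stride amplitude above the
  spectral floor (stride target clamped to ≥ 0.07 g, i.e. sinusoid
  amplitude `A = π/2 · stride ≥ 0.11` g). Walking is laid down as whole
  30-s duty cycles inside a 09:00–19:00 activity window, so observed
  walking time is exactly one third of true walking time and the
  duty-cycle adjustment is exact in expectation. Within walking bouts
  `vm = 1 + A sin(2π(cadence/60)t)`, decomposed onto the axes with a random
  per-day device orientation (exercising the vector-magnitude invariance),
  plus 0.02 g sensor noise.
- **Mobility**: each participant-day visits `n_locations − 1` satellites
  along a random-bearing ray, out-and-back at 60 km/h, with equal pauses at
  each satellite; home hosts the night. Departure, arrival and return times
  are snapped to GPS fix times so detected pauses begin and end on observed
  fixes. GPS emits one fix per 5 s during on-windows — 12 fixes per
  minute-long window identify pauses and headings amply at a fraction of
  1 Hz data volume — with 5 m fix noise.
- **Missingness**: each day is valid (coverage ~U(1380, 1440) min) with
  probability 0.741, collected-but-invalid (U(240, 959) min) with
  probability 0.13, else missing entirely. Valid days stay near-complete so
  truncation never eats into the planted evening schedule; invalid days are
  excluded from all analyses, exactly as the valid-day rule dictates. The
  0.741 is applied as a day-level rate; the corresponding published figure
  is a participant-level data-sufficiency share, which is not identifiable
  at day resolution.
- **Idle accelerometer data** default to one keep-alive sample per minute
  outside walking bouts (`idle_accel = "keepalive"`): idle bouts contribute
  to no gait measure while preserving coverage accounting, at ~2% of the
  full-rate file size. `idle_accel = "full"` renders the complete
  duty-cycled idle stream when stream-level fidelity itself is under test.

What the generator does **not** emulate: physiologically realistic gait
waveforms (walking is a pure tone), urban road networks (travel is
straight-line), device OS/battery missingness mechanisms (coverage is an
i.i.d. draw), EQ-5D-5L items linked to the digital measures (items are
drawn independently; only PROMIS and optionally ECOG drive the measures),
and correlation between reported smartphone use and data quality (planted
null). Passing tests therefore demonstrate that the pipeline recovers what
it is designed to measure under its own model assumptions — not that those
assumptions hold in any real cohort.

## Problem sizes and numerical choices

- Recovery and calibration simulations use 200 replicate cohorts of 85
  participants × 4 waves (the study's sampling design); raw-sensor
  end-to-end checks use 5–16 participants over 20–28 days, which already
  exercise every code path at full per-day data density.
- Miniature cohorts scale the survey alignment window with their survey
  spacing (e.g. ±3 days for weekly surveys): with ±10-day windows on a
  20-day study, every window covers nearly the whole study, aligned
  observations within participant become near-identical, and PROM fits are
  ill-conditioned. The study-scale default remains ±10 days.
- The cohort timezone defaults to UTC so every synthetic day is exactly
  86,400 s; DST-shifted 23/25-hour days would otherwise make the
  time-conservation check ambiguous twice a year. Real data in any IANA
  timezone are supported, with days defined local-midnight-to-midnight.
- Duplicate sensor timestamps keep the first record; GPS fixes with
  reported accuracy worse than 100 m (configurable) are dropped before
  segmentation, since such fixes masquerade as movement.
- `steps_adjusted` is rounded to an integer (counts are reported as
  integers); cadence and stride acceleration are missing, not zero, on days
  without detected walking.

## Known limitations

- The spectral classifier assigns a single dominant frequency per on-bout
  (bouts are only 10 s); seconds within a bout share that frequency.
  Sub-bout cadence changes are smoothed over.
- The gap-imputation rule cannot reconstruct excursions that begin and end
  inside one off-period; distance is a lower bound under such behaviour.
- Wald intervals are first-order; with very few participants they can be
  anticonservative (the smartphone-use OLS fits at n = 8 participants show
  this in the example workflow). The calibration stage quantifies coverage
  at the study scale, where it is nominal (90–98%).
- The home definition requires at least one night-time pause; participants
  never observed at night have undefined home time.
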