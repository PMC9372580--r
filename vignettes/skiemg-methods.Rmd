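---
title: "On-snow EMG and turn-cycle analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{On-snow EMG and turn-cycle analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skiemg)
```

## The problem

During alpine ski training, athletes repeat near-maximal runs separated by
chairlift rides. Whether this repetition measurably alters neuromuscular
function — muscle activation intensity, activation timing, spectral fatigue
markers — is hard to assess in the field: the signals are contaminated by
vibration, the workload is organized in turns rather than steady-state
effort, and athletes differ far more between sessions than within them.

`skiemg` implements a complete analysis chain for this setting:

1. **Signal conditioning** of five thigh-muscle surface EMG channels
   (vastus medialis, rectus femoris, vastus lateralis, biceps femoris and
   the medial hamstrings, right leg) sampled at 1926 Hz, plus a tri-axial
   trunk accelerometer and knee/hip electrogoniometers at 148 Hz.
2. **Turn-cycle segmentation** from the accelerometer resultant.
3. **Per-turn scalar metrics**: EMG amplitude in %MVC, mean power
   frequency, burst (activation) duration, turn and run times, joint-angle
   extrema, movement amplitude and peak angular velocities.
4. **Mixed-model inference** comparing the first and last run of a session
   with variance-ratio (ICC) effect sizes and a coefficient-of-variation
   repeatability decomposition.
5. A **synthetic-session generator** with full ground truth, so every stage
   is verifiable without any athlete recording.

## Signal conditioning

All filters are Butterworth designs applied zero-phase
(forward–backward). Zero-phase application is a deliberate choice: turn
segmentation and EMG–kinematics alignment must not be distorted by phase
lag. The cost is that the effective magnitude response is the *squared*
single-pass response, which the tests account for explicitly. Edge handling
uses odd-reflection padding of at least `3 / f_c` seconds, long enough for
the near-DC cut-offs (0.5 Hz) to settle; a plain forward–backward pass with
zero initial state produces multi-second transients at such cut-offs.

The per-stage parameters, all overridable per call:

| Stage | Filter | Parameters |
|---|---|---|
| EMG band-pass | 2nd order | 20–500 Hz |
| Baseline removal | moving average | 1 s, centred, reflection-padded |
| RMS envelope | sliding RMS | 125 ms, centred, 1-sample hop |
| Artifact rule | threshold | envelope mean ± 6 SD, per run |
| Angle low-pass | 4th order | 0.5 / 1 / 2 / 2.5 Hz (DH/SG/GS/SL) |
| AccR low-pass | 4th order | 0.8 / 1 / 2 / 3 Hz (DH/SG/GS/SL) |
| Burst envelope | 4th order low-pass of \|EMG\| | 1 / 2 / 4 / 7 Hz (DH/SG/GS/SL) |

Three decisions here were genuinely open:

* **Sliding versus disjoint RMS epochs.** The 125-ms RMS is computed as a
  centred sliding window with a one-sample hop (continuous envelopes, one
  value per sample), not as disjoint 125-ms blocks; edge samples use a
  truncated window.
* **Artifact statistics per run.** The mean ± 6 SD thresholds are computed
  over each run segment rather than the whole session, because snow
  conditions and vibration level drift between runs. Visual artifact
  screening is replaced by an automatic surrogate: a (cycle, muscle) pair is
  dropped when more than 5% of its EMG samples are artifact-flagged
  (configurable).
* **Burst-envelope calibration.** The "linear envelope" for activation
  timing is the rectified band-passed EMG low-passed at the discipline
  cut-off. Low-passing *unrectified* EMG at a few hertz would annihilate
  it, so rectification is mandatory. The rectified mean of a Gaussian
  interference pattern is only `sqrt(2/pi)` ≈ 0.80 of its RMS, while the
  activation threshold (20% of the MVC maximal RMS) is expressed in RMS
  units; the envelope is therefore rescaled by `sqrt(pi/2)` so that both
  live on the same scale. `calibrate = "none"` restores the plain
  rectified mean.

MVC normalization follows the standard maximal-voluntary-contraction
procedure: per trial, the peak force and the maximal 500-ms sliding RMS
inside the force plateau (the longest interval at ≥ 90% of the trial peak,
with the full RMS window inside it) are extracted; trials whose peak force
falls within 10% of the best trial are retained; the per-muscle reference
is the mean of the retained maxima.

## Turn segmentation

The trunk-worn accelerometer yields the resultant acceleration
`AccR = sqrt(x^2 + y^2 + z^2)` (in g). Between edge sets the skier unloads,
so the low-passed AccR dips at every turn switch. Switches are detected as
**local minima of the low-passed AccR**. Descriptions of this step in the
field alternate between "minima of AccR" and inflection points of its
derivative; the derivative's upward zero-crossing *is* the AccR minimum, so
the two readings coincide for well-behaved arches and the minimum form is
implemented, with a minimum-separation guard of `0.5 / f_c` seconds between
accepted minima (deeper minimum wins) to suppress noise-induced doubles.

A **cycle** is one right turn followed by one left turn. With right-leg
instrumentation the right turn loads the instrumented leg in the
*inside-leg* (IL) role and the left turn in the *outside-leg* (OL) role.
Turn polarity (whether the first switch of a run opens a right turn) is not
derivable from AccR alone and is exposed as a configuration key
(`polarity`), defaulting to right-first; a run starting mid left turn drops
its leading partial turn. Cycles never cross run boundaries, and the first
and last cycle of every run are flagged excluded as unrepresentative
entry/exit turns.

Each cycle half is resampled to 100 points by linear interpolation on its
own time base (200 points per cycle, percentages integral). The
edge-change ("unloading") phases — 0–10%, 40–60% and 90–100% of the cycle —
are masked from EMG averaging; interior boundaries are half-open, so the
mask retains exactly 120 of 200 points.

## Per-turn metrics

* `rms_pct_mvc`: mean of the %MVC envelope over retained grid points per
  leg half.
* `mpf_hz`: power-weighted mean frequency of a single untapered
  periodogram over 20–500 Hz, computed on native-rate band-passed samples
  of the central 20–80% of each half (the time-domain image of the
  edge-phase mask), not on the normalized grid — spectra from resampled
  grids would be distorted.
* `burst_ms`, `burst_pct`: total time the calibrated linear envelope
  exceeds 20% of the MVC maximal RMS inside the turn, in milliseconds and
  as % of the turn; multiple supra-threshold intervals are summed, with no
  hysteresis or minimum-duration criterion.
* `turn_time_ms`, `run_time_s`: inter-switch intervals and run-marker
  spans.
* `min/max_angle_deg`, `peak_flex/ext_vel_dps` per turn and leg;
  `amplitude_deg` over the whole cycle (both legs), since the movement
  amplitude is a property of the double turn.

Run selection pairs the **first and fourth** runs (labels `First`/`Last`),
falling over to runs 2 and 5 when run 1 or 4 is incomplete, and to the
first/last complete runs for shorter sessions. Undefined metrics (zero
spectral power, fully masked halves) propagate as missing and are dropped
listwise by the model layer.

## The mixed-model layer

Each outcome is modelled per discipline as a random-intercept model over
skier-sessions:

```
value ~ run + leg + run:leg + (1 | session_id)
```

with `run`-only fixed effects for cycle-level outcomes (movement amplitude,
run time). Models are fitted by maximum likelihood with `glmmTMB`. The
response family is chosen automatically among **normal**, **lognormal**
(a normal model on log responses, with the log-transform Jacobian
`2 * sum(log y)` added to its AIC so the three AICs refer to the same
response density) and **gamma** (log link; no canonical choice exists, the
log link keeps effects multiplicative like the lognormal), by lowest
comparable AIC. Families requiring positivity leave the race when any
response is non-positive.

From the fitted components the package derives:

* `r2m = var_fixed / (var_fixed + var_random + var_residual)` and
  `r2c = (var_fixed + var_random) / (...)`, with `var_fixed` the empirical
  variance of the fixed-effect linear predictor over the observed design
  and, for the gamma family, the latent-scale residual variance
  `trigamma(shape)`;
* `ICC_adj = var_random / (var_random + var_residual)` and
  `ICC_cond = var_random / (var_random + var_residual + var_fixed)`, so
  that `r2m + ICC_cond = r2c` holds identically;
* Wald z p-values per coefficient (the factors are two-level, so
  coefficient tests are term tests at the reference level of the other
  factor), with α = 0.05 and no multiplicity correction — the report has
  one row per test so users can apply their own;
* estimated marginal means on the balanced run × leg grid with Wald 95%
  CIs, and Last − First differences per leg, back-transformed to the
  response scale for log-link families;
* the effect classification: *negligible* when p ≥ α **or**
  `|ICC_adj − ICC_cond| < 0.01` (the fixed effect adds nothing to the
  denominator, so significance without size), otherwise bucketed by
  `ICC_cond`: < 0.5 *very strong*, 0.5–0.75 *strong*, 0.75–0.9 *moderate*,
  > 0.9 *small*. The 0.01 tolerance operationalizes "approximately equal"
  and is configurable;
* a CV decomposition, each component as percent of the grand mean:
  `cv_random` (between sessions), `cv_intra` (within session),
  `cv_syst` (fixed-effect spread, `100 * sqrt(var_fixed) / mean`). The
  systematic component's exact published form is not available, so this
  square-root-variance form is an explicit interpretation; for log-link
  families latent variances map to CVs via `sqrt(exp(v) - 1)`.

A random-intercept variance collapsing to zero is reported with a
`singular` flag, not an error.

## The synthetic-session generator

The generator emulates the statistical and temporal structure the analysis
assumes, with full ground truth:

* **EMG** channels are band-limited Gaussian carriers (4th-order band-pass
  of white noise, ±40 Hz around the muscle's configured spectral centre,
  unit RMS) amplitude-modulated in %MVC, so the mean power frequency has a
  known target. The per-turn envelope has cosine ramps and a flat top
  covering the retained (edge-masked) part of the turn, so the true mean
  drive of a turn equals its flat-top level; burst on/off times have a
  closed form.
* The **true per-turn drive** is built additively: per-muscle base level
  (inside leg), an outside-minus-inside leg offset, an optional additive
  run effect on runs after the first, a per-session random intercept
  (between-session variance) and turn-to-turn noise (residual variance).
  The turn noise is centred within each leg so the configured leg effect
  is *exactly* recoverable from the truth table.
* **AccR** rests at the arch maximum between runs, enters and leaves each
  run through smooth half-arches, and traces one arch per turn —
  minima exactly at switch times; vibration is additive Gaussian noise per
  axis. The lateral axis alternates sign with turn direction.
* **Angles** oscillate at turn frequency between configured extrema
  (180° = full extension), flexing mid-turn.
* **Artifacts** are 50-ms in-band (150 Hz) oscillatory transients at 30 SD
  of the run signal, at Poisson times — a DC pulse would be removed by the
  20 Hz high-pass edge and never trip the ±6 SD envelope rule.
* **MVC trials**: three per muscle group with peak forces at 1.00 / 0.96 /
  0.88 of the best (exercising the 10% retention rule) and plateau EMG at
  the configured maximal RMS.

Discipline defaults were chosen once from typical race-training courses:
mean turn durations 0.80 / 1.47 / 2.15 / 2.30 s and 45 / 30 / 25 / 20
turns per run for SL / GS / SG / DH, within the regulation ranges (SL
40–60, GS 25–50, SG 15–40, DH 15–35 turns per run). The default run effect
is zero — repeated runs leave the drive unchanged — so the out-of-the-box
generator expresses the stability null; leg asymmetries default to
outside-leg dominance (+10 %MVC for the vastii, +5 for the hamstrings)
with the rectus femoris inverted (−10), matching the biarticular muscle's
inside-leg role. Raw EMG scale is arbitrary (0.2 mV maximal RMS per
muscle): only %MVC-relative quantities are meaningful, and the metrics are
invariant to the absolute scale by construction.

What the generator does **not** emulate: ski–snow interaction forces,
terrain and gate geometry, snow-condition drift across runs, co-activation
structure between muscles, within-turn drive shape changes, or
non-stationary vibration spectra. Passing tests therefore demonstrate that
the pipeline recovers what it claims from signals with the *assumed*
structure, not that the assumptions hold on any particular athlete
recording.

## Numerical choices and degenerate inputs

* Filters refuse cut-offs at or above Nyquist; band edges are prewarped by
  the bilinear design (`signal::butter`), and tests compare measured gains
  against the tan-warped closed form.
* A zero-variance envelope yields an empty artifact mask, not an error.
* Burst time is clamped to the turn duration (sample-count discretization
  could otherwise exceed it by a fraction of a sample).
* `detect_turn_switches` errors below 3 minima ("no complete cycle");
  `build_cycles` requires 4 switches inside a run.
* Ties between close minima are broken by depth (deeper wins), then time.
* Cycle-level metrics carry `NA` legs; CVs of outcomes with non-positive
  grand means (flexion velocities) are reported as missing.

## Problem sizes used in the shipped checks

The package's own test suite and the acceptance script run entirely on
synthetic data at sizes chosen to exercise every code path at interactive
speed: one clean 4-run × 30-turn giant-slalom session for segmentation and
metric recovery; 25 replicates of 40 sessions × 30 turns for
variance-component recovery; 200 null replicates of 12 sessions × 6 turns
for type-I calibration; 50 replicates for CI coverage; and an 8-session
end-to-end null pipeline for the stability property. These sizes are the
package's own verification choices; all thresholds (±3% switch recovery,
5% duration recovery, binomial envelope on the 5% test level, ≥90%
negligible classifications under the null) are stated in the tests
themselves.

## Known limitations

* Wald z tests are anticonservative for very small numbers of sessions;
  the type-I calibration is demonstrated at 12+ sessions, not at 2.
* The lognormal family's emmean differences are computed by regridding to
  the response scale; for strongly skewed data these are differences of
  geometric-mean-type quantities, not raw-mean differences.
* Spectral structure (MPF) carries no between-session variance in the
  default generator, so MPF models are frequently singular — flagged, and
  classified correctly as negligible, but not a realistic portrait of
  between-athlete spectral variability.
* Only the discipline-specific cut-off tables of the four standard
  disciplines are provided; pooling super-G and downhill into a "Speed"
  class is a reporting convention, the signal layer always uses the
  specific discipline's cut-offs.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- synth_config("GS", seed = 42)
res <- run_pipeline(pipeline_config(synth = cfg, n_sessions = 6,
                                    out_dir = "gs_demo", seed = 42))
subset(res$report, metric == "rms_pct_mvc",
       select = c(channel, family, p_run, icc_adj, icc_cond,
                  run_effect_class, diff_OL, diff_IL))
```

The bundle written to `gs_demo/` contains the tidy metrics table, the
cycle-interval audit file, the per-outcome model reports (CSV and JSON)
and a provenance file sufficient to re-run the analysis bit-identically.
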