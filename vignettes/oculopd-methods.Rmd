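---
title: "Methods: saccade and pupillometry analysis for early-PD screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saccade and pupillometry analysis for early-PD screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Oculomotor control degrades early in Parkinson's disease: pro-saccades
(reflexive movements toward a new stimulus) slow down and become less
accurate, and anti-saccade direction errors (looking at the stimulus when
instructed to look away) are corrected less often. Pupil dynamics carry
additional autonomic and cognitive signal: during a saccade task the pupil
repeatedly constricts and recovers, and the frequency content of that
"wavy" diameter trace differs between patients and controls. `oculopd`
implements the full analysis chain for a VR-based assessment of both
phenomena, together with a synthetic cohort generator so that every stage is
testable without access to clinical recordings.

## Task protocol

Each task (pro- and anti-saccade) consists of 40 trials: 1 s central
fixation, a lateral stimulus for 1.2 s, then 2 s rest — 4.2 s per trial,
168 s per task. Twenty stimuli appear on each side in seeded random order.
Trial windows are half-open `[start, end)` in seconds from recording start.
The stimulus eccentricity is not part of the protocol statement; we default
to 10 degrees horizontal, configurable. The sample rate is likewise
unspecified upstream; the default is 120 Hz, typical for VR-embedded eye
trackers and comfortably above twice the 19 Hz spectral cutoff. The 1-min
black-screen rest between test sets is modelled as an inter-task gap only;
it never interrupts a 40-trial block.

## Synthetic cohorts: the stated world

The generator's defaults are anchored to the published group summaries: the
PD and control profiles use the printed latency (269.5 ± 116.4 vs
283.3 ± 100.3 ms), peak velocity (424.3 ± 197.9 vs 536.5 ± 141.6 deg/s),
behavioural rates (pro-saccade correctness 0.848 vs 0.933, anti direction
errors 0.575 vs 0.622, error correction 0.268 vs 0.451) and correction
delay (247.1 ± 236.8 vs 310.0 ± 191.6 ms). Pupil band oscillations sit at
2.1, 11.8, and 17.4 Hz with amplitudes from the anti-saccade
frequency-amplitude table (PD 0.48/0.10/0.07 mm, control 0.25/0.17/0.12 mm).
Values the source does not state were chosen once at realistic scales and
not revisited: primary-saccade gain 0.85 ± 0.10 (PD, hypometric) vs
0.95 ± 0.07, pupil baseline 3.6 vs 3.9 mm, constriction depth 0.30 mm,
white pupil noise 0.05 mm, blink rate 0.08 Hz.

Design choices worth knowing:

* **Saccade waveform.** Minimum-jerk position profiles, because they are
  smooth, standard, and give the closed-form relation
  `duration = 1.875 · |amplitude| / peak velocity` that the tests exploit.
* **Latency and correction-delay distributions.** A 100 ms-shifted (80 ms
  for correction delays) gamma matched to the stated mean and SD, rather
  than a truncated normal. Truncating a normal at a physiological floor
  would bias the mean upward by ~15 ms and defeat the parameter-recovery
  tests; latency distributions are also genuinely right-skewed.
* **Peak-velocity ceiling.** Draws are truncated to [150, 650] deg/s. The
  ceiling is physiological for 10-degree saccades and also marks the point
  beyond which a 120 Hz recording cannot support 5%-accurate peak-velocity
  recovery (at 650 deg/s a 10-degree saccade spans ~3.5 samples).
* **Completion-time mechanism.** Hypometric primaries trigger corrective
  saccades after a ~150 ms intersaccadic pause. Because the PD profile is
  more hypometric, PD trials need corrections more often, which lengthens
  their time-to-complete — the mechanism behind the group contrast in
  average completion time, as in real oculomotor data.
* **Blinks.** Poisson onsets (0.08 Hz), uniform 100-300 ms duration,
  binocular, zeroing validity and pupil samples. The source only states
  that blink-contaminated data were excluded.
* **Seeding.** One root seed; subject seeds are drawn once from it; every
  stochastic stage (schedules, draws, forests, folds) is seeded from its
  inputs, so cohorts and reports are byte-reproducible.

What the generator does **not** emulate: head movement, calibration drift,
monocular blinks and asymmetric eye signals, non-stationary oscillation
amplitudes, saccadic intrusions during fixation, and any coupling between
saccadic behaviour and pupil dynamics. A green test therefore establishes
that the pipeline recovers what the generative model puts in — not that the
published clinical effect sizes are correct.

## Preprocessing

Samples are flagged when tracker-invalid, when pupil diameter leaves
[1.5, 9] mm, or when the pupil slew rate exceeds 10 mm/s. Slew is evaluated
on a 250 ms moving average (after bridging invalid samples), because the
stated world legitimately contains oscillations up to ~0.5 mm at 2.1 Hz and
sample noise whose raw sample-to-sample differences would otherwise trip
the limit everywhere; the slew check targets gross tracker glitches.
Pupil gaps up to 75 ms are linearly interpolated. Gaze is never
interpolated — interpolation across a gap could fabricate or destroy a
saccade — so any trial whose fixation-through-stimulus span contains a
longer gap is excluded with a reason code. All three thresholds are
configurable; none is stated upstream.

## Saccade detection and scoring

Velocity is estimated by first differences on the staggered (midpoint)
grid, smoothed with a 5-point quadratic Savitzky–Golay kernel. Events open
when |v| ≥ 30 deg/s and extend hysteretically while |v| ≥ 20 deg/s; events
shorter than 10 ms or smaller than 1 degree are dropped. Event amplitude
comes from the position trace at the event bounds; peak velocity is
re-estimated from an 8x cubic-spline upsampling of the position inside the
event, which keeps the worst-case error under ~3% for saccades as brief as
3.5 samples (raw central differences at 120 Hz would underestimate fast
peaks by 8-15%).

Scoring: the first supra-threshold saccade after stimulus onset defines
latency; responses under 80 ms are discarded as anticipatory (standard
practice, unstated upstream). A pro trial is correct when that saccade is
stimulus-ward and gaze then dwells within 2 degrees of the target for at
least 100 ms; time-to-complete runs from stimulus onset to the start of
that stable dwell, which is why it exceeds latency. An anti trial scores a
direction error when the first saccade is stimulus-ward; the error counts
as corrected when a later contra-ward saccade reaches the mirror location
within the trial, and the correction time spans error-saccade offset to
corrective-saccade onset. Per-subject summaries aggregate to the 14
standard parameters (accuracy, latency, min/avg completion time, avg/max
velocity per task, plus the anti error-correction rate and correction
time); the error-correction rate is undefined (NA) for subjects without
direction errors.

## Pupil spectra

Pupil traces (excluded-trial spans removed) are split into consecutive
complete 10 s windows; each window is linearly detrended (slow diameter
drift otherwise dominates the low bins), transformed with a plain
rectangular-window DFT, and read out as `2/N · |X(f)|` on the 0.1 Hz grid
from 0 to 19 Hz — 191 bins per (task, eye), averaged across windows. Ten
second windows give the 0.1 Hz resolution natively; shorter segments are
zero-padded to the next 10 s multiple (normalisation stays `2/N` with `N`
the true sample count, so off-multiple segments leak and are avoided by the
windowing). Whole-task windowing is an interpretation: per-trial 1.2 s
epochs cannot resolve 0.1 Hz. Band labels follow the published convention —
low 0-6 Hz, medium 7-12 Hz, high 13-19 Hz — with boundaries at 6.95 and
12.95 Hz so that every 0.1 Hz bin has exactly one band (the integer labels
leave 6-7 and 12-13 Hz unassigned).

## Statistics

Every feature (14 saccadic parameters and each of the 191 x 2 x 2 frequency
bins) is compared between groups with a Shapiro–Wilk-gated test: pooled
two-sample t when both groups pass normality at 0.05, Mann–Whitney U
(normal approximation, continuity-corrected) otherwise; constant samples
fall through to the nonparametric branch. The pooled (not Welch) t is
deliberate: it reproduces the published summary statistics exactly.
Significance is uncorrected α = 0.05 per bin — matching the upstream
policy under which the band counts were produced — and the band-count
report tallies significant bins per (task, eye, band) with both-eye totals.
No multiple-testing correction is applied; treat per-bin flags as
descriptive.

## Diagnostic classification

Six feature sets (basic 14; pro-saccade spectra 382; anti-saccade spectra
382; each spectra set plus basic; all 778) feed a random forest: 500 CART
trees, Gini splits, sqrt-p feature subsampling, bootstrap resampling,
majority vote. The forest is implemented in compiled code inside the
package. Evaluation is stratified 5-fold cross-validation repeated 10
times (the upstream evaluation scheme is unstated; this is the standard
choice for n = 68). Feature selection — keep columns whose group
comparison is significant, fall back to the 5 smallest p-values when none
is — runs inside each training fold to avoid selection leakage, which is
stricter than the ambiguous upstream wording. Missing cells (e.g.
correction rate for error-free subjects) are imputed with training-fold
medians. Metrics are accuracy, class-macro precision and recall, and F1 as
their harmonic mean, averaged over repeats; per-fold predictions are kept
in the report for audit.

In the synthetic world the basic saccadic parameters are themselves highly
discriminative (the group shifts are at the published scale across all 14
parameters), so the all-features model beats the basic model by a small
margin rather than the published 0.79-vs-0.63 gap; only the ordering is
asserted, on ≥ 20 seeds.

## Numerical and degenerate-input policy

Zero pooled variance with unequal means yields a signed-infinity t
sentinel; identical constant samples give p = 1. Saccades whose requested
peak velocity would compress them below 3 samples are slowed to keep 3;
waveform synthesis refuses durations under 2 samples. Sampling below 60 Hz
is refused for detection, below 2x the cutoff for spectra. Scoring with
zero valid trials is an error, as is classification with a single class or
fewer than 2 subjects per class.

## Known limitations

The type-I calibration of the per-bin tests is checked by simulation under
the package's own null (identically distributed cohorts); bins within one
cohort are correlated through shared subject-level draws, so calibration is
averaged over independent cohort pairs. The classifier comparison inherits
the generator's optimism (clean group structure, no site or device
effects). CSV is the only interchange format; no device-specific ingestion
is provided.
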