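---
title: "Saccade-related potentials and eye features in structured visual search: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saccade-related potentials and eye features in structured visual search: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(srpsearch)
```

# The task and the scientific question

`srpsearch` analyzes co-registered EEG and eye-tracking data from a
structured visual search task. Fifteen "system" locations, arranged in
three rows of five columns on a 1280 x 1024 display, are highlighted one
after another for about one second each. Each highlighted location shows
either a target string or a non-target string; two to four targets appear
per trial, and after the sequence the observer clicks the locations that
held targets. Memory load is manipulated with a concurrent auditory
arithmetic task: under *high load* the observer must also solve a spoken
six-number sum; under *low load* the same audio plays but is ignored.

Three families of signals carry information about target detection and
encoding:

* **Saccade-related potentials (SRPs)** — EEG epochs time-locked to the
  peak velocity of the saccade toward each highlighted location. Targets
  elicit a larger positive parieto-central deflection around 500 ms
  (a P300-family response).
* **Fixation duration** — cumulative time gaze stays within 150 px of the
  highlighted stimulus during the two seconds after highlight onset;
  longer for targets than non-targets and for later-reported (hit) than
  forgotten (miss) targets.
* **Pupil size** — mean pupil diameter over the same on-stimulus samples;
  larger under high load and larger for misses than hits, consistent with
  a workload interpretation of encoding failure.

The package implements the full analysis chain plus a synthetic-data
generator that emulates the task and these signal structures with known
ground truth, so every stage can be validated end to end.

# The processing chain

The pipeline order is fixed: resample to 256 Hz; clean EOG; detect and
select saccades; condition EEG; epoch; extract eye features; group
statistics; single-trial classification.

## EOG cleaning and saccade detection

1. **Despiking** (`despike()`): samples deviating more than 5 SD from the
   channel mean (SD computed over the whole channel, for determinism) are
   cut with 50 ms padding and linearly interpolated.
2. **Blink removal** (`detect_and_remove_blinks()`): a 2-100 Hz band-passed
   copy of the vertical EOG is thresholded at 3 SD; supra-threshold runs
   are merged (gaps < 100 ms), padded by 100 ms, and interpolated in the
   original signal. Blinks are positive deflections, so the threshold is
   one-sided. Because the threshold adapts to the filtered trace's SD, a
   hypothetical *blink-free* recording would see the threshold fall until
   vertical-saccade transients cross it; the detector is meant to operate
   on recordings that contain blinks, where those transients sit well
   below 3 SD.
3. **Velocity** (`gaussian_derivative_filter()`): convolution with the
   derivative of a Gaussian, sigma = 8 samples (31.25 ms at 256 Hz),
   normalized so a unit-slope ramp maps to its slope. Kernel truncated at
   4 sigma, reflected-edge padding.
4. **Candidates** (`find_candidate_saccades()`): runs where |velocity|
   exceeds 4 SD of the trace (runs closer than 20 ms merged), one
   candidate per run at the peak.
5. **Selection** (`select_saccade_of_interest()`): within 100-800 ms after
   highlight onset (endpoints inclusive), the first horizontal candidate
   whose sign matches the horizontal displacement of the
   stimulus-to-stimulus transition; failing that, the first matching
   vertical candidate. Purely vertical transitions skip the horizontal
   test (the horizontal sign of a zero jump is undefined, so the rule
   falls through to the vertical channel). For the first highlight of a
   trial there is no previous stimulus; gaze rests at screen centre
   between trials, so the centre serves as the previous position. The
   adjacency constraint and the direction rule apply within trials only.

## EEG conditioning and epoching

Bad channels are those whose 0.5-32 Hz SD exceeds 5x the median channel
SD; they are replaced by an inverse-distance-weighted average of the 4
nearest good channels on the 2D 10-20 montage, computed on *unfiltered*
data. The data are then re-referenced to the mean of the good channels
(still unfiltered) and band-passed 0.5-32 Hz with a 4th-order zero-phase
Butterworth (the band is prescribed; the filter family and order are the
package's choice). Epochs span [t0, t0 + 1 s) from the saccade velocity
peak (256 samples), baselined on the **first 100 ms of the epoch** — i.e.
post-saccade, as the analysis prescribes, rather than the more
conventional pre-stimulus window — and epochs whose within-epoch SD on any
channel exceeds 50x that channel's across-epoch median SD are discarded.
The "50x SD" rule is deliberately read as a robust across-epoch median
criterion; the reference population was an open choice and is
configurable.

## Eye features

Gaze is recalibrated with a global least-squares affine transform mapping
per-highlight median gaze positions (0.3-1.0 s after onset, excluding
pre-saccadic samples) to the true stimulus centres; collinear geometry
falls back to translation only. Fixation duration is the count of valid
on-stimulus samples (distance <= 150 px) in [onset, onset + 2 s) divided
by the 60 Hz eye rate — a dropout-robust reading of "time on stimulus".
Pupil size is the mean over those same samples; a median variant is
exposed via `pipeline_params(pupil_stat = "median")` because the summary
statistic is ambiguous in the source analysis description (mean is the
default).

## Group statistics and classification

Per participant and condition, epochs are averaged and then the seven
parieto-central channels (CP1, P3, Pz, PO3, PO4, P4, CP2) are averaged;
grand averages are unweighted means over participants. Pointwise paired
two-sided t-tests run at every epoch sample (3.9 ms steps) with alpha
0.05, corrected with Benjamini-Hochberg over all 256 samples of the epoch
(the correction family was not fully specified; the whole epoch is the
package's choice and is configurable). Scalar features use paired t-tests;
behavioral correlations use Pearson r.

Single-trial classification uses linear SVMs (cost 1, an open choice) with
stratified 5-fold cross-validation. Features: EEG voltages 250-1000 ms
after the saccade velocity peak over all 32 channels (6144 dimensions),
EOG voltages over the same interval, fixation duration, pupil size, and
their combinations. Per fold, features are standardized with training-fold
statistics only, and the training majority class is randomly subsampled to
the minority count; the test fold is never touched. Above-chance
performance uses the exact one-sided binomial tail with alpha 0.05 on the
pooled test count. Hit-vs-miss contrasts run only when a session has at
least 10 misses (in practice, the high-load condition).

# The synthetic-data generator

`generate_schedule()` draws highlight orders by a greedy random walk
(uniform among unvisited locations satisfying the adjacency constraint:
at most two steps horizontally with one vertically, or two vertically with
one horizontally; dead ends restart the trial). Target counts are uniform
on {2, 3, 4} at uniform locations. `simulate_behavior()` misses each
target with probability `base_miss x curve[serial position]`; the curve is
U-shaped in hit rate (primacy/recency) and normalized to mean 1, and base
rates default to expected hit rates of 0.73 (high load) and 0.96 (low
load). A miss spawns a false alarm with probability 42/72, matching the
observed ratio of average false-alarm to miss counts.

`synthesize_recording()` renders:

* **Gaze/EOG**: logistic-sigmoid steps per saccade; the sigmoid midpoint
  defines the ground-truth velocity peak. Saccade latencies are drawn per
  condition from normal distributions anchored to the reported latency
  table (e.g. high-load hits 199 +/- 43 ms, misses 284 +/- 97 ms),
  redrawn into [110, 780] ms so rendered saccades stay inside the
  detection window. Rise time follows the main sequence
  (25 ms + 2.5 ms/deg), and saccades larger than 15 deg undershoot by 12%
  with a corrective saccade 150 ms later. EOG = 12 uV/deg of gaze
  rotation plus white noise (5 uV).
* **Dwell structure**: after a condition-dependent dwell (hits 750 ms,
  misses 600 ms, non-targets 500 ms, SD 150 ms — chosen to produce
  fixation-duration orderings of realistic size, as the absolute values
  are not printed in the source), gaze drifts slowly off the stimulus;
  during the inter-trial reporting pause (18 s, standing in for clicking
  responses and typing the math answer) it drifts back to screen centre.
  Disengagement and recentering are drifts, not saccades, because
  reporting-phase kinematics are out of scope; this also keeps the
  velocity trace quiet between trials, which the 4 SD detection threshold
  implicitly assumes.
* **EEG**: per channel, 1/f pink noise (SD 8 uV) plus white noise (2 uV),
  with a Hann-shaped positive bump (width 0.3 s) injected 0.5 s after
  each saccade's velocity peak, spatially weighted by a parieto-central
  Gaussian topography. Amplitudes default to 5 uV (targets) and 1 uV
  (non-targets), with hit and miss amplitudes equal — reflecting the
  finding that miss traces overlap hit traces — and configurable for
  power studies. Note that average re-referencing deterministically
  attenuates a spatially broad response: the recoverable difference is
  `amplitude x (mean topography over the 7 analysis channels - mean over
  all 32)`, about 55% of the injected value with the default topography.
* **Pupil**: load-dependent baseline (4.3 / 4.7 mm, near the reported
  ~4.5 mm operating point; the load difference magnitude is a documented
  free parameter), a slow drift (SD 0.1 mm), white noise, and a +0.25 mm
  increment while a to-be-missed target is fixated.
* **Blinks**: Poisson (10/min), positive Hann deflections of 400 uV and
  100-250 ms width in VEOG, with gaze marked invalid during blinks; 2% of
  eye samples are additionally invalid.
* **Measurement error**: the recorded gaze stream passes through an
  affine miscalibration (scale 1.03, offset (15, -10) px) that
  `recalibrate_gaze()` recovers.

Ground truth (saccade peak times, latencies, dwells, blink intervals,
injected amplitudes) is always returned, and every detector is scored
against it in the test suite.

## What the generator does and does not emulate

It reproduces the *statistical structure* the analysis relies on:
condition-dependent latencies, dwells, response amplitudes, pupil effects,
blinks, dropouts, miscalibration, and the task's timing. It does not
attempt biophysically realistic EEG (no volume conduction or
corneo-retinal dipole artifacts in the EEG channels), reporting-phase
kinematics, or pupil foreshortening. Passing tests therefore demonstrate
that the pipeline correctly recovers the structures it assumes, at
realistic noise levels — not that it would be robust to every artifact of
real co-registered recordings (in particular, residual ocular artifacts
in EEG are absent by construction).

# Numerical and design choices

* Threshold SDs are global per channel/trace, for determinism.
* Interpolation of cut artifacts is linear; padding is 50 ms (spikes) and
  100 ms (blinks), covering filter ringing.
* The epoch window is half-open [t0, t0 + 1 s) with exactly 256 samples;
  the baseline is floor(0.1 x 256) = 25 samples and is zeroed exactly.
* Grid coordinates are 0-based (row, col) with row 0 at the top; screen
  coordinates have y growing downward, HEOG positive for rightward and
  VEOG positive for upward gaze. The generator and detector share these
  conventions.
* The middle grid location coincides with the screen centre, so a trial
  opening there induces no saccade; such events carry NA ground truth and
  are excluded from recovery denominators.
* Latency draws are truncated into [110, 780] ms; for the low-load miss
  condition (mean 267, SD 245 ms) truncation shifts the realized mean
  upward, so recovery is always assessed against the generated ground
  truth rather than the nominal parameter.
* Degenerate inputs: all-flagged despike input, empty channel sets,
  upsampling requests, invalid bands, all-bad channel sets and
  zero-variance tests raise explicit errors; conditions with zero
  observations are reported as missing, never as zero.

# Problem sizes in the tests

The reference experiment ran 21 humans through 88 trials per load; the
test suite uses scaled-down studies chosen to keep the full suite
comfortably re-runnable while retaining statistical power: 20 simulated
participants with 10 (low) / 16 (high) trials per load for the
effect-direction study, 20 participants with 6 + 6 trials for the null
calibration, ten 6-trial sessions for ground-truth recovery, and
miniature 2-participant studies for determinism checks. With 16 high-load
trials a participant presents about 48 targets and 13 misses, enough for
the hit/miss contrast gate (>= 10 misses) in most simulated participants;
participants below the gate are excluded pairwise, mirroring the
treatment of the low-load condition.

# Known limitations

* The adjacency constraint is enforced within trials only; whether it
  binds across trial boundaries is unspecified in the task description.
* The BH correction family (all 256 epoch samples) may differ from the
  original analysis, which did not state its family; significant-interval
  lengths are therefore comparable only qualitatively.
* The blink detector's adaptive threshold over-triggers on recordings
  without blinks (see above); this is inherent to the method, not a bug.
* EOG-based detection misses a small fraction of saccades whose step is
  destroyed by a coincident blink; the unmatched fraction (typically
  3-7% here, 10% reported for the human data) quantifies this.
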