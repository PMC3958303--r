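---
title: "Gait-phase detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-phase detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitphase)
```

## The problem and the signals

A finite-state controller for a robotic lower-limb prosthesis consumes a
phase identifier: which part of the gait cycle the wearer is in, updated at
the sensor rate. `gaitphase` detects that identifier online from eight
wearable-sensor signals sampled at 100 Hz: the vertical ground reaction
force under each foot (`grfL`, `grfR`, N, from instrumented insoles), the
longitudinal centre of pressure under each foot (`copyL`, `copyR`, mm,
origin at the toes and increasing toward the heel; undefined while the foot
is in the air), the hip and knee flexion angles of both legs (deg, from
IMU-derived kinematics) and the sagittal angular velocity of each foot
(`gyroL`, `gyroR`, rad/s). Two derived signals carry most of the
discriminative information: `sumAng`, the sum of all four joint angles
(total lower-limb flexion: near zero standing, oscillating during walking),
and `grfDiff`, the mean absolute GRF difference over the past 50 samples
(0.5 s), a lateral-asymmetry measure that is near zero standing and large
throughout walking.

Units are fixed (N, mm, deg, rad/s, s) and the sampling rate is fixed at
100 Hz; a trial with a different rate fails validation rather than being
resampled. The unloaded-COP sentinel is `NA` — never a magic number inside
the valid 0–300 mm range — and every COP comparison is defined `FALSE` when
the sentinel is present. The contact epsilon below which a foot counts as
unloaded is 5 N.

## The rule-based state machine

A steady-state stride is divided into four phases — left single stance (flag
11), left–right double stance (12), right single stance (13), right–left
double stance (14) — bracketed by quiet standing (5), initiation (6) and
termination (4). Each state has one conjunctive condition row; the rows are
evaluated on every sample (`eval_rows()`), and `detector_step()` turns them
into an online detector: the firing row's flag becomes the current flag, and
when nothing fires the previous flag is retained. Two corrections of
apparent typos in the published form of the rule table are applied and
marked in the source: the initiation unload condition compares both feet
(`grfL < QSgrf || grfR < QSgrf`), and the right–left double-stance flexion
condition reads `sumAng > minAng`, mirroring the left–right row.

**Tie-breaking.** Several rows can fire on one sample, so the detector
applies a fixed priority: double-stance rows (12, 14) over single-stance
rows (11, 13) over initiation (6) over quiet standing (5) over termination
(4). The first three levels are forced by logic: the double-stance
conditions are strict supersets of the foot-contact conditions, and each
single-stance row implies the initiation row under its GRF-asymmetry and
flexion conditions, so any other order would make those states unreachable.
Quiet standing is ordered *above* termination for the same kind of reason: a
subject standing relaxed with both feet loaded above `QSgrf` satisfies the
termination row and both quiet-standing rows simultaneously and
indefinitely, so with termination first, flag 5 could never be reached from
a realistic standing posture. Quiet standing and initiation are mutually
exclusive by the threshold invariant `init2 <= init1`.

**Strict mode.** The default (`free`) mode lets any firing row set the flag,
which matches a detector that may skip an undetected phase and resynchronise
at the next one. `strict` mode additionally requires the firing row to be a
legal transition out of the current state in the state diagram (5→6, 6→5,
6→11/13, 11→12, 12→13, 13→14, 14→11, 12→4, 14→4, 4→5), emulating a
prosthesis controller that pauses until an allowed transition arrives. The
initial state is `UNKNOWN` (0) until the first row fires; the recommended
protocol starts trials with several seconds of quiet standing, which the
symmetric fully-loaded condition detects on the first sample.

**Thresholds.** The thirteen thresholds are subject-specific in practice.
The defaults express them relative to body weight \(W\) (N) and insole
length \(L\) (mm): `QSgrf` = 0.30 W, `stanceL` = `stanceR` = 0.05 W,
`init1` = 0.15 W, `init2` = 0.10 W, `sumQS` = 15°, `sumAngInit` = 25°,
`sumAngTerm` = 20°, `minAng` = 10°, `midCOP` = 0.45 L, `toeCOP` = 0.30 L,
`minG` = 0.2 rad/s, `termG` = 0.3 rad/s. These are this package's choices,
not published values: contact thresholds at 5% of body weight are
comfortably above insole noise yet fire within a sample or two of
touch-down; the asymmetry thresholds put `init2` below `init1` so the
quiet-standing and initiation rows cannot overlap; the COP thresholds split
the insole into a toe region (below 0.30 L) and a heel-to-midfoot region
(above 0.45 L) with a guard band between them. COP thresholds are in
millimetres (the same unit as the signal), not normalised insole fractions.
All thirteen can be overridden through a JSON/YAML config
(`read_thresholds()`), which rejects unknown or missing keys.

## The HMM alternative

The supervised baseline trains one hidden Markov model per walking phase on
labelled segments and classifies a sliding window of the current and past 9
samples by the maximum forward log-likelihood over the four models
(deterministic tie-break by ascending flag). Shorter windows at a trial
start emit `UNKNOWN` rather than padding. Design choices where the approach
leaves room:

* **Observation vector.** The same signal combination the rules use, in
  fixed order (`grfL`, `grfR`, `grfDiff`, `copyL`, `copyR`, `sumAng`,
  `gyroL`, `gyroR`), with the COP sentinel replaced by the mid-insole
  coordinate plus a binary `loaded` indicator per foot, and per-feature
  location/scale standardisation shared by the four models (classification
  is therefore invariant to common affine rescalings of the features).
* **Emissions and topology.** A single diagonal-covariance Gaussian per
  hidden state, three states per phase, initialised from the temporal
  thirds of each training segment with a left-to-right-leaning transition
  prior and a small seeded jitter; continuous sensor observations and small
  training sets argue against richer emission families.
* **EM.** Baum–Welch to a local optimum; stopping at a relative
  log-likelihood improvement below 1e-6 or 200 iterations; the training
  log-likelihood is non-decreasing across iterations (a property the test
  suite asserts).
* **Variance floor.** Emission variances are floored at 1e-2 in
  standardised units. The floor matters: phase-boundary samples make the
  binary contact features only *almost* constant within a phase, and with a
  much smaller floor a single mismatched binary sample outweighs the whole
  window by orders of magnitude, degrading windows that straddle a
  transition. At 1e-2 a binary mismatch still costs ~25 nats — dominant but
  not pathological.
* **Numerics.** Classification likelihoods use an exact log-space forward
  recursion; the scaled recursion can underflow to a zero scaling factor on
  windows far from a model's support. Inside EM, where segments are
  pure-phase, the scaled recursion is used (with a guard) because it yields
  the posteriors directly.

The three training designs are reproduced by `build_training_sets()`:
intra-subject (each subject's own first `n_train` walks, 3 by default),
inter-subject (the other subjects' training walks, excluding the verified
subject) and pooled (everyone's training walks); evaluation is always on
walks outside the training set.

## The synthetic generator

No amputee recordings are distributable, so every test and benchmark runs on
`simulate_trial()`, which produces labelled trials with the qualitative
morphology of insole/IMU walking data: per stance a double-bump GRF (a sine
lobe with a Gaussian mid-stance dip, peaks ≈ 1.1 W, valley ≈ 0.8 W) and a
linear heel-to-toe COP ramp (0.85 L → 0.10 L); `sumAng` oscillating between
≈ 5° (mid double stance) and ≈ 70° (mid-swing) as a periodic Gaussian dip
around each double-stance midpoint; biphasic ± 3 rad/s gyro bursts during
swing; cosine-blended initiation and termination ramps; Gaussian noise per
channel. Defaults: body weight 600 N, stride period 1.0 s (one stride per
second, a normal walking speed), stance fraction 0.62 (so each double
stance is 12% of the stride), insole length 260 mm, 3 s of standing on
either side. The prosthetic side scales that leg's GRF amplitude by 0.9 and
its stance time by 0.95; the time asymmetry is kept mild deliberately, so
the shortened prosthetic-side double stance stays at least ~5 samples long
— the event remains resolvable at 100 Hz, as it must for any detector to be
evaluable. Labels are assigned analytically from the phase schedule, so
they satisfy the state-diagram topology by construction and realised
stance/swing durations match the parameters within one sample.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: compensatory movement patterns of prosthesis
users, sensor axis misalignment and soft-tissue artefacts, slopes, stairs,
turning, and non-Gaussian or correlated sensor noise. Synthetic amplitudes
are not claims about any study population. One structural consequence of
the analytic labels is worth knowing: `grfDiff` is a 50-sample trailing
mean, so detection of initiation and termination necessarily lags the
scheduled label boundaries by up to ~0.5 s. That lag is physics of the
windowed statistic, not detector error, and it does not affect the walking
phases, which are what the success metric scores.

## Evaluation choices

`segment_phases()` run-length encodes the walking flags, absorbing runs
shorter than a debounce (3 samples by default) into their neighbours and
bridging same-flag segments split by a shorter-than-debounce gap. A
ground-truth phase occurrence counts as correctly recognised iff some
detected segment of the same flag overlaps it by at least one sample *and*
that segment sits consistently in the cyclic phase order 11→12→13→14→11:
its neighbouring detected walking segments must be 1–2 forward steps away,
one skipped (undetected) phase being allowed. The overlap requirement, the
debounce value and the skip allowance are this package's choices; the
per-phase ratio (100 × recognised / total occurrences of the type) follows
the standard definition. Reports carry both the arithmetic mean of the four
per-phase ratios and the count-weighted (pooled) mean, since both
conventions appear in the literature; aggregation across trials or subjects
always pools counts, never averages ratios. Because the HMM bank has no
classes for standing, initiation or termination, its output outside the
walking maneuver is arbitrary; detectors are therefore scored on the
walking span of each trial (`walking_span()`), which leaves the rule-based
detector's scores unchanged and gives the HMM a meaningful sequence
context.

## Problem sizes and degenerate inputs

The shipped tests and the acceptance script use desk-scale designs chosen
as reasonable miniatures of a gait study: trials of 3–10 strides, banks
trained on 3 walks (mirroring small clinical training sets), benchmarks of
2–4 subjects with per-subject draws of weight (550–750 N), cadence
(0.9–1.15 s/stride), duty factor (0.60–0.64), amplitude asymmetry
(0.85–0.95) and stance-time asymmetry (0.92–0.98). Degenerate inputs are
defined rather than accidental: empty trials yield empty outputs; an empty
GRF history is an error; constant training segments hit the variance floor
instead of failing; a truth sequence without walking phases is a scoring
error; thresholds violating `init2 <= init1` or `toeCOP <= midCOP` are
rejected at construction.

## Known limitations

* Thresholds are static per trial; no online adaptation or auto-tuning is
  provided (the defaults substitute for the interactive per-subject tuning
  a clinician would do).
* The rule count and exact threshold values of any particular deployment
  are subject-specific; results on synthetic data bound what the method can
  do under its own assumptions, not its clinical performance.
* The HMM path is an offline-trained baseline, not an online learner; banks
  are frozen after training.
* Initiation/termination timing is detected with the inherent lag of the
  50-sample asymmetry window (see above); applications needing sharp
  initiation events should use a dedicated event detector.
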