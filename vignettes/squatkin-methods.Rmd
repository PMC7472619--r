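---
title: "Methods: dual-system single-leg-squat kinematics and concurrent validity"
author: "squatkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-system single-leg-squat kinematics and concurrent validity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squatkin)
```

## What the package computes

`squatkin` models the measurement situation of a concurrent-validity experiment
for lower-limb kinematics: the same single leg squat is captured simultaneously
by a laboratory optical system (reflective marker clusters at 120 Hz, the
reference standard) and by a set of four body-worn orientation sensors (50 Hz,
the system under evaluation). Sensors and marker clusters sit on the sternal
manubrium (trunk), the sacrum (pelvis), the lateral mid-thigh and the
anteromedial mid-shank. Three joints are analysed — spine (trunk vs sacrum
segment), hip (thigh vs sacrum) and knee (shank vs thigh) — and five variables
are read at the instant of peak knee flexion: knee flexion, hip flexion, hip
ab-/adduction, spine flexion and spine lateral flexion.

Because no raw recordings of such an experiment are publicly deposited, the
package includes a rigid-body squat simulator that renders both measurement
modalities with known ground truth. Everything downstream (filtering, pose
fitting, quaternion angles, peak extraction, agreement statistics) is exercised
against that simulator.

## Kinematic conventions

Every segment carries the same right-handed local frame: `x` anterior, `y`
superior (longitudinal), `z` to the subject's right. Orientations are unit
quaternions, scalar first `(w, x, y, z)`, Hamilton product, with
`quat_multiply(q1, q2)` meaning "apply `q2`, then `q1`". A joint is the
orientation of the distal (secondary) segment expressed in the proximal
(primary) segment's frame; all joint angles are zeroed in the upright
calibration pose.

Let `v` be the image of the longitudinal axis `u = (0, 1, 0)` under the
calibrated joint rotation, i.e. the second column of its rotation matrix `R`.
The sensor-side units are:

* **tilt** `= atan2(v·anterior, v·longitudinal)` — sagittal-plane deviation;
* **sway** `= asin(v·lateral)` — frontal-plane deviation (elevation of the
  longitudinal axis out of the sagittal plane);
* **swing** `= angle(u, v) ≥ 0` — total deviation of the longitudinal axis;
* **twist** — the signed rotation about the longitudinal axis, obtained from
  the swing–twist factorisation `q = swing ⊗ twist` (`twist` has its rotation
  axis along `u`, `swing` perpendicular to it).

The optical side uses the intrinsic Euler sequence sagittal → frontal →
transverse: first a rotation about the mediolateral axis, then about the
anterior axis, then about the longitudinal axis.

**Why sway is an arcsine, not an arctangent ratio.** With the conventions
above, `v·anterior = R[1,2]`, `v·longitudinal = R[2,2]` and
`v·lateral = R[3,2]`. The intrinsic sequence gives, for any rotation,
`sagittal = atan2(R[1,2], R[2,2])` and `frontal = asin(R[3,2])` — exactly the
tilt and sway definitions used here. Tilt and sway are therefore algebraically
identical to the Euler sagittal and frontal angles for *every* rotation, and
the two measurement paths can only differ through noise, filtering and
sampling, never by definition. Had sway been defined as
`atan2(v·lateral, v·longitudinal)`, the two systems would disagree
systematically at deep flexion (about 7.6° for a hip flexed 61° with 8° of
frontal deviation), an artefact of the projection rather than of either
instrument; a validity analysis built on that definition would partly measure
the definition gap. Twist differs from the Euler transverse angle away from
the planar case; the transverse plane is not among the analysed variables.

**Swing.** The total longitudinal deviation angle is reported alongside
tilt/sway/twist. It is redundant in the planar cases (`swing = |tilt|` when
sway is zero and vice versa) and is provided as a magnitude summary; no
validity claims are made for it.

**Signs.** Flexion, adduction, internal rotation and homolateral spine lateral
flexion are positive. In these frames that requires a sagittal sign flip for
the knee (the distal shank rotates opposite to the proximal joints' flexion
direction) and frontal/transverse flips for left-leg stance
(`sign_convention()`), so anatomical directions stay positive regardless of
side.

**Gimbal lock.** The Euler sequence is singular at ±90° frontal; outputs
within 1° of the singularity are flagged. Tilt/sway remain finite there
(`asin` is regular; `atan2` degenerates only at the isolated antiparallel
configuration), which is the practical argument for quaternion-based units.

## Calibration

Both systems are zeroed with the subject standing upright. The optical path
takes each cluster's marker template from the calibration capture, so
Procrustes poses are already expressed relative to upright; the sensor path
right-multiplies each segment stream by the inverse of its averaged upright
orientation (chordal mean over the 1 s static window, hemisphere-aligned).
Segment-level calibration is used rather than only joint-level zeroing because
it cancels a constant sensor mounting rotation *exactly*: an observed stream
`q_seg(t) ⊗ m` calibrated by `(q_seg(0) ⊗ m)⁻¹` leaves `q_seg(t) ⊗ q_seg(0)⁻¹`,
independent of `m`. Zeroing only the joint-level relative orientation leaves a
conjugation by the distal mount (a residual of roughly 0.4° for a 5° mount at
75° flexion). The joint-level `calibrate()` step is still applied afterwards;
at zero noise it is the identity.

A consequence shared by both paths (and by their real-world counterparts) is
that anatomical axes are inherited from the calibration pose, assumed upright
and world-aligned: rotating an entire dataset (movement, calibration and
templates) by a common world rotation conjugates every calibrated joint
rotation, leaving rotation magnitudes and fit residuals unchanged but mixing
the planar components. The test suite asserts exactly those invariants.

## Signal processing

Marker trajectories (movement and calibration alike) are low-pass filtered
with a 4th-order Butterworth at 3 Hz, applied forward and backward so the
phase response is zero — peak-timing analysis forbids phase lag — at the cost
of a squared magnitude response (≈ 84 dB attenuation at 10 Hz instead of 42).
The series is padded by odd reflection (1 s per end, trimmed afterwards) and
the filter is run on the deviation from the boundary value, so a constant
passes exactly and startup transients decay inside the padding. The squat
fundamental (0.25 Hz for a 4 s movement) is attenuated by less than 0.1%.
Filtering is applied to marker coordinates, never to angles; the sensor stream
is consumed as delivered by the device fusion.

Cluster pose uses the orthogonal Procrustes solution (Kabsch SVD with a
reflection guard) per frame, centroid-aligned, with per-frame RMS residuals
(the per-frame loop is compiled C++ for throughput; a test cross-checks it
against a direct optimisation oracle). Gaps up to 0.1 s are filled by linear
interpolation per coordinate; longer gaps are an error naming the cluster and
interval.

The 50 Hz sensor stream is aligned to the 120 Hz optical timeline by spherical
linear interpolation of *orientations* (shorter arc, constant angular speed),
after which angles are recomputed. Interpolating finished angle curves instead
would commute only in the planar case; orientation-space interpolation is the
coherent reading of spherical interpolation.

## Peak extraction

The peak is the global maximum of the knee sagittal curve, ties resolved to
the earliest frame, endpoints flagged. Each modality is read at its own peak
instant (the two systems were treated as paired per-trial summary readings; a
shared clock is not assumed), switchable to a shared reference instant via
`run_config(peak_mode = "shared")`. No sub-sample interpolation is applied:
at squat speed the knee curve changes by well under 0.1° across one 8.3 ms
frame near its flat maximum.

## Statistics

Per variable and trial, paired across subjects: mean, SD and 95% CI per
system (t quantiles, n−1 SD — t-based intervals reproduce the published
worked examples from printed means and SDs at n = 44); the paired mean
difference new-minus-reference with t-based 95% CI; and a correlation whose
kind is gated by Shapiro–Wilk normality of both vectors at α = 0.05 (Pearson
if both pass, otherwise Spearman on average ranks). Strength labels are
piecewise-constant on |r|: poor < 0.3 ≤ fair < 0.6 ≤ moderate < 0.8 ≤ very
strong < 1 = perfect. Significance is α = 0.05 per test, deliberately without
multiple-testing correction, matching the analysis being emulated; the report
footer says so. The mean-difference direction is fixed and documented because
published tables of this kind are not always internally consistent about it.

## The simulator: what it emulates, and what it does not

A four-segment chain (trunk, pelvis, thigh, shank; segment lengths of a
≈ 1.75 m adult) performs a metronome-timed squat: every joint angle follows
`peak × sin²(πt/4)` over 4 s — smooth, zero velocity at the ends, peak at 2 s
(descent 2 s, ascent 2 s). Frontal-plane profiles share the sagittal time
course scaled to their own peaks; the protocol being emulated fixes timing
only. The ankle stays fixed, so pelvis drop follows geometrically from knee
and hip flexion. The upright pose at t = 0 is exact.

Per-subject peak angles are drawn from Normal(mean, SD²) with the reported
first-trial descriptive scale as defaults — knee 73.8 (9.1), hip 60.8 (14.7),
hip sway −8.1 (17.1), spine 13.8 (10.9), spine sway 3.8 (5.7) degrees — plus
within-subject between-trial jitter (SD 3°, the order of the trial-to-trial
drift visible in per-trial summary tables). The default cohort is 44 subjects
× 3 trials = 132 trials.

Noise model, chosen once on physical grounds:

* **Soft-tissue artefact**: a correlated Gaussian displacement process
  (Ornstein–Uhlenbeck, correlation time 0.5 s) per segment with 3-D RMS
  amplitude 10 mm at the thigh and 5 mm elsewhere — scaled down from the up to
  40 mm reported for thigh STA, since cluster plates on taped sites move less
  than individual skin markers. 70%/30% of the amplitude is cluster-common
  (rigid plate displacement, which cancels in the centroid-aligned pose fit)
  versus per-marker independent (skin/plate deformation, which does corrupt
  orientation).
* **Marker measurement noise**: white, 0.5 mm per axis.
* **Sensor orientation noise**: an AR(1) rotation-vector process, stationary
  SD 1°, correlation time 0.5 s — fusion output error drifts slowly; white
  orientation noise would be unphysical and would bias the extracted maximum.
* **Mounting misalignment**: constant per subject, rotation-vector SD 5°
  (cancelled exactly by calibration, see above).
* Marker clusters are 80 × 120 mm four-marker plates.

Not emulated: raw accelerometer/gyroscope signals and the fusion filter
itself, marker occlusion and relabelling, camera geometry, failed or
unbalanced trials, heading drift between the two systems' world frames, and
any systematic (bias-like) disagreement between modalities beyond what the
noise model produces. Passing tests therefore demonstrate that the *pipeline*
is correct and that under plausible noise the agreement pattern has the
reported shape (near-ceiling sagittal correlations, weaker frontal/spine
ones); they do not certify any physical instrument.

## Numerical choices

Quaternions are renormalized after algebra (unit norm enforced to 1e-9);
`q` and `−q` are treated as one rotation everywhere, with hemisphere
continuity enforced along streams and before averaging. SLERP falls back to
normalized linear interpolation, flagged, when the 4-vector dot product is
below 1e-6 in magnitude (a ≈ 180° rotation gap has no unique shortest arc).
The swing–twist factorisation is singular for a 180° rotation exactly
perpendicular to the twist axis; the twist is then set to identity and the
frame flagged. The calibration mean is the chordal (component-wise) mean,
adequate for the sub-degree spread of a static window. Per-trial and
per-subject seeds are derived deterministically from the base seed (kept
below 2³¹), so any trial can be regenerated from the manifest alone.

Problem sizes used by the shipped checks: single trials for exact-recovery
properties; 1 000 replicate cohorts for the distributional check of the
population sampler; 10⁴ random rotations for the swing–twist recomposition
bound; 20 seeded full cohorts (44 × 3) for the stochastic agreement pattern.

## Known limitations

* Tilt/sway/twist and the Euler sequence agree by construction here; systems
  with other sequences (e.g. joint coordinate systems) would show additional
  definitional differences that this package does not model.
* One static calibration cannot separate sensor mounting from segment posture;
  subjects are assumed truly upright and world-aligned at calibration.
* The simulator's noise amplitudes are calibration knobs with physically
  motivated defaults, not measurements; absolute error magnitudes should not
  be read as claims about any commercial device.
* TRC/C3D ingestion is out of scope; the documented CSV dialects (and their
  readers) are the interchange format.
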