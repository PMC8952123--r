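---
title: "Assessing 3D relative motion between a limb and an exoskeleton link"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing 3D relative motion between a limb and an exoskeleton link}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relmo3d)
```

## The measurement problem

A lower-limb exoskeleton is coupled to the user through compliant physical
interfaces. The device link and the thigh therefore do not move as one
rigid body: the link slips and rotates relative to the limb during gait.
That relative rotation is an ergonomic performance indicator — it
represents transmission loss, possible discomfort, and undesired degrees
of freedom — and it is what this package measures, in all three anatomical
planes, from standard optical motion capture.

The quantity of interest is the frame-by-frame rotation of the exoskeleton
link expressed in the thigh frame,

$$R_{exo/th} = R_{exo/O} \, R_{th/O}^{-1},$$

decomposed into three plane angles: RotZ about the mediolateral axis
(sagittal plane, where actuation happens and misalignment is largest),
RotX about the anteroposterior axis (frontal plane) and RotY about the
longitudinal axis (transverse plane).

## Frame construction and its numerical care

Both frames are built per video frame from markers:

* thigh: proximal reference $t_{up}$ = midpoint of EPSD and EASD, distal
  reference $t_{low}$ = midpoint of the condyle markers CMD and CLD;
  longitudinal axis $y = t_{up} - t_{low}$, mediolateral axis
  $z = CLD - t_{low}$, anteroposterior $x = y \times z$;
* exoskeleton: $y$ = knee-motor-to-hip-motor marker vector,
  $z$ = normal of the plane spanned by the link cluster (R3, R4, R5),
  $x = y \times z$.

Markers are noisy, so the raw $y$ and $z$ are never exactly orthogonal and
the matrix of unit vectors is not exactly a rotation — which would break
the transpose-as-inverse step above. Each frame is therefore
re-orthogonalized keeping $y$ verbatim: $x = y \times z$ is normalized,
then $z$ is recomputed as $x \times y$. The longitudinal axis is the
anatomically anchored one, so the correction is pushed into the
mediolateral axis, which is the least well-defined by the markers anyway.
Every emitted frame satisfies $RR^\top = I$ and $\det R = +1$ to within
1e-9 (enforced by tests on random rigid poses).

Two degeneracies are handled by invalidating the frame rather than
raising: a required marker in an unfilled gap, and degenerate geometry
(an axis below 1e-6 mm, or $y \parallel z$, e.g. a collapsed cluster).
Invalid frames propagate as `NA` angles and any gait cycle containing one
is dropped from statistics, with the reason logged.

The cluster normal's sign depends on the arbitrary ordering of R3/R4/R5,
so $z_{exo}$ is sign-corrected to point laterally: it must have positive
dot product with the thigh's mediolateral axis in the same frame; when no
thigh frame is available the sign that points the first valid frame's
$z_{exo}$ toward global +Z is used throughout. (The construction's
anteroposterior axis $x_{exo} = y \times z$ is treated as anteroposterior,
mirroring the thigh construction, even though device descriptions
sometimes label it loosely.)

## Euler convention

The decomposition sequence is a genuine design choice: different
sequences give slightly different numbers once rotations exceed a few
degrees. The default is intrinsic **Z–X–Y** — sagittal first — because
the dominant rotation between thigh and link is sagittal and extracting
it first minimizes cross-talk into the small frontal and transverse
angles. The convention is recorded in every `relative_angle_series` and
is configurable (`"ZXY"`, `"XYZ"`, `"ZYX"`); comparisons between datasets
are only meaningful within one convention. Within the principal domain
(middle angle in (−90°, 90°)) compose-then-decompose is the identity to
1e-9 degrees (property-tested on 10,000 random triples). At gimbal lock
the standard degenerate convention is used (third angle zeroed, the sum
assigned to the first) and the frame index is reported in
`$gimbal_lock`; physically plausible interface motion never approaches
±90° about the frontal axis.

## Signal conditioning

Three conditioning steps precede the statistics, all configurable:

* **Gap filling** (`fill_gaps()`): capture pipelines encode gaps as zero
  samples; interior gaps up to `max_gap = 10` frames (0.1 s at 100 Hz)
  are filled with an interpolating cubic spline through the marker's
  valid samples. Longer gaps and leading/trailing gaps are left missing —
  extrapolation would invent data — and simply invalidate the affected
  frames.
* **Marker smoothing** (`smooth_trajectories()`): a zero-phase 4th-order
  Butterworth low-pass at 6 Hz, the standard choice in gait analysis:
  voluntary walking kinematics live below ~5 Hz while optical noise is
  broadband. Without it, broadband angular noise inflates per-cycle
  max–min ranges by a degree or more; with it, range estimates recover
  prescribed slippage amplitudes to a few percent. Filtering is applied
  per contiguous gap-free run (gaps are never bridged) with
  odd-reflection end padding to suppress filter edge transients.
* **Offset handling** (`remove_offset()`): the donning of the device
  leaves a static misalignment. The default is `"none"` — the offset is
  itself a meaningful outcome and the headline tables retain it — with
  `"first_sample"` and `"static_pose"` available when only orientation
  *changes* are wanted.

## Event detection and segmentation

Heel strikes are detected on the heel marker's vertical position:
low-pass filter (zero-phase Butterworth, order 4, 6 Hz), central-difference
acceleration, local maxima above an adaptive threshold (mean + 1 SD of
the acceleration) separated by at least 0.5 s, larger peak winning ties
inside the refractory window. The vertical axis (default global +Y),
cutoff, order, threshold multiplier and refractory period are all
parameters; the defaults are ordinary gait-analysis practice. The
acceleration peak at impact is sharp, so detection is exact to ±1 frame
on synthetic trials at the default noise level (tested over 20 seeds).

One gait cycle spans two consecutive heel strikes of the same foot. The
first and last cycles of a trial are excluded (gait acceleration and
deceleration make them unrepresentative), cycles containing invalid
frames are dropped and logged, and each kept cycle is linearly resampled
to 101 points so the sub-phase boundaries — flat foot 10 %, heel off
50 %, toe off 73 %, heel strike 100 % — index exact samples. Resampling
an already-101-frame cycle is the identity, and linear signals stay
linear, to 1e-9.

## Statistics

Per axis, over the kept cycles:

* **Overall mean**: the average angle over all cycles and samples.
* **Range of rotation**: per-cycle max − min, summarized by mean, sample
  SD (n−1 denominator) and CV = 100·SD/mean. Ranges are computed per
  cycle — a dispersion summary of a single pooled curve would have no
  SD/CV — and the range of the across-cycle mean curve is reported
  separately (`mean_curve_range`) for transparency, since averaging
  flattens extremes.
* **Sub-phase differences**: the across-cycle mean curve is evaluated at
  0/10/50/73/100 % and differenced per sub-phase; absolute values feed
  the summary table and the signed values are retained, because
  decreases are physically meaningful.
* **Cross-correlation consistency**: for every unordered pair of cycles,
  the zero-lag normalized cross-correlation of the mean-centered curves
  (the Pearson correlation); the score is the pairwise mean. This is the
  simplest estimator consistent with the bounds +1 (identical shape) and
  −1 (phase opposition); a lag-maximized variant is available via
  `max_lag` for pipelines that want phase-tolerant similarity.
  Zero-variance cycles cannot be correlated; their pairs are skipped and
  counted.

Every statistic is tested to 1e-12 against naive double-loop oracles, and
the whole summary is scale-consistent: doubling all angles doubles means
and ranges, and leaves CV and cross-correlation unchanged.

## The synthetic generator

`simulate_trial()` is first-class, tested code, not a fixture: it is how
the pipeline's accuracy is established. It builds a thigh oscillating in
the sagittal plane (default 20° amplitude about a 10° offset at a 1.1 s
stride period), attaches the anatomical markers at fixed body-frame
positions on a 45 cm femur (mid-range adult anthropometry; condyle
markers ±55 mm, proximal markers ±50 mm, a 150 mm link cluster), composes
the exoskeleton frame as thigh × prescribed relative rotation, and plants
heel strikes by adding a short Gaussian impact dip (10 mm deep, 50 ms
wide) to a smooth 30 mm stride oscillation of the heel — so the filtered
vertical acceleration peaks exactly at the planted frames.

The default prescribed relative motion — offsets (−0.7°, 1.1°, 30°) and
slippage amplitudes (3.5°, 2.2°, 3.4°) about X/Y/Z — mirrors the
magnitudes reported for thigh interfaces of a unilateral lower-limb
exoskeleton in walking studies: a large constant sagittal offset from
donning, near-zero frontal/transverse offsets, and single-digit-degree
cyclic slippage. Marker noise is isotropic Gaussian, 0.5 mm SD by
default; gaps are inserted by explicit spec and encoded as zero spans in
C3D fixtures, matching capture-pipeline conventions.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: soft-tissue artifact beyond white marker noise
(real skin motion is structured and gait-phase-locked; here the
prescribed slippage itself plays that role), marker occlusion patterns
correlated with pose, non-sinusoidal slippage waveforms, inter-subject
variability of gait timing, and camera-system distortions. Statistical
recovery results (offsets to 0.5°, amplitudes to 10 %) are statements
about this noise model, not about any particular hardware.

## Problem sizes

The validation suite uses 12 s trials at 100 Hz (about 9–11 strides, 8
kept cycles), 50 random rigid poses for frame recovery, 1000 random
orthonormal pairs against an explicit-inverse oracle, 10,000 Euler
round-trip triples and 20 seeded replicates for the stochastic recovery
checks; `scripts/acceptance.R` simulates a six-subject study at the
generator defaults. These sizes give stable statistics while keeping the
full validation run to seconds.

## Known limitations

* The Euler sequence of published interface-slippage tables is often
  unstated; cross-study numeric comparison is convention-sensitive,
  especially once angles exceed ~10°.
* The C3D support is a deliberate subset (Intel processor type,
  labeled points, float or scaled-integer storage, no analog channels);
  files from exotic acquisition systems may need conversion.
* Sub-phase boundaries are fixed percentages, not detected per cycle;
  subjects with atypical phase timing are summarized on the nominal
  grid.
* The method measures orientation difference only; translational
  slippage and interface forces need additional instrumentation.
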