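---
title: "Measuring head posture from facial landmarks: model, estimator, and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring head posture from facial landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facepose)
```

## The measurement problem

Abnormal head posture — a habitual face turn, head tilt or chin-up/down
position — is a clinically meaningful sign in strabismus, nystagmus and
other ocular motility disorders, and quantifying it usually requires either
a goniometer-style device strapped to the head (a cervical range of motion,
CROM, device) or subjective estimation. A webcam-based alternative tracks
facial landmarks in video and infers the head's orientation from their
2D configuration. This package implements the geometry of that inference
and the statistical machinery used to validate such an instrument.

The head posture is expressed as three clinical Euler angles plus a metric
position:

* **yaw** (face turn), positive toward the subject's left;
* **pitch** (chin up/down), positive chin-up;
* **roll** (head tilt), positive toward the subject's right shoulder;
* **(tx, ty, tz)**, the position of the head in the camera frame in
  millimetres.

All interfaces use degrees. Pose is reported *relative to the camera*: the
implicit clinical assumption is that the subject's shoulders and the camera
are aligned (a seated subject facing the device), which is the standard
arrangement for this kind of measurement; the package makes no attempt to
track the trunk.

## Face model and camera

The tracker fits one fixed, rigid "simplified face": a 68-landmark 3D
table in the standard layout (17 jawline, 5 + 5 eyebrows, 9 nose, 6 + 6
lid margins, 20 lips), shipped as a versioned CSV resource and loaded by
`canonical_model()`. Three properties of this table are contractual, and
everything downstream depends only on them:

* exactly 68 points with the standard region counts;
* mirror symmetry about the midsagittal plane under the standard
  left–right index pairing;
* pupil centres (centroids of the two lid-margin groups) exactly 65 mm
  apart, with the model origin at their midpoint.

The 65 mm figure is the conventional adult interpupillary distance, and it
is what anchors metric scale: a monocular camera cannot observe absolute
size, so all distances are reported *as if* the subject had a 65 mm IPD. A
subject whose true IPD is 70 mm is reported at a distance biased by the
factor 65/70 ≈ 0.93 — a documented, systematic property of the method, not
noise (the estimator test suite verifies exactly this factor). The rest of
the table (nose protrusion ≈ 24 mm, jaw depth ≈ 45 mm, average adult
proportions) only has to be plausibly face-shaped and non-coplanar; no test
or result depends on its exact values beyond the invariants above.

The camera is an ideal pinhole: `u = cx + f·X/Z`, `v = cy + f·Y/Z`, camera
frame x right, y down, z forward into the scene, image origin top-left.
When intrinsics are unknown, `default_camera()` assumes focal length =
image width (≈53° horizontal field of view, typical of consumer webcams)
and the principal point at the image centre. Lens distortion is not
modelled.

### Euler convention

Rotations compose intrinsically in the order yaw → pitch → roll (yaw about
the model's vertical axis, pitch about its left–right axis, roll about the
face normal). This order and the sign conventions above are stated in every
file header and CLI help text, because no universal convention exists and
silent mismatches are the classic failure mode of pose pipelines.
`rotation_to_euler()` inverts `euler_to_rotation()` to 1e-9; at gimbal lock
(|pitch| = 90°) the in-plane ambiguity is folded into yaw and roll is
reported as 0, an arbitrary but fixed tie-break.

## The pose estimator

`estimate_pose()` inverts the projection in two stages.

**Initialization** (`initialize_weak_perspective()`): under a
weak-perspective (scaled-orthographic) approximation the mapping from model
coordinates to centred pixels is affine; a least-squares affine fit
followed by orthonormalization (SVD projection to the nearest rotation)
gives the rotation, and the fitted scale s gives the depth tz = f/s. This
closed form is biased for nearby subjects (perspective is not orthographic)
but always lands within a few degrees — close enough for local refinement.

**Refinement** (`refine_pose()`): damped Gauss–Newton on the sum of squared
pixel reprojection errors over the six pose parameters, with
Levenberg-style multiplicative damping (×10 up on a rejected step, ÷10 on
an accepted one) and central-difference Jacobians. Defaults: at most 50
iterations, convergence when every update falls below 1e-6° and 1e-4 mm.
On clean data this converges in 3–5 iterations to machine precision — the
test suite verifies recovery to better than 1e-3° and 0.1 mm over a grid of
350 poses spanning ±30° yaw, ±20° pitch, ±50° roll and 0.8–1.5 m. The
optimizer never raises on bad data: divergence, insufficient landmarks
(fewer than 6 visible — the minimum that over-determines 6 degrees of
freedom) or a behind-camera excursion all return an untracked estimate.

**Confidence.** Real landmark trackers report a goodness-of-fit confidence
that falls with occlusion, rapid motion and extreme pose. Here confidence
is a clamped linear map of the normalized residual:

> confidence = clamp(1 − residual / residual_scale, 0, 1),

where the residual is the RMS reprojection error divided by the *projected
inter-pupil pixel distance*. That normalization makes the number invariant
to subject distance and image resolution, so one threshold is meaningful
across cameras. With the default `residual_scale = 0.10`, a perfect fit
scores 1, clean noiseless synthetic fits score ≈1, ~1 px landmark jitter at
1.2 m scores ≈0.9, and unstructured input scores 0. A frame counts as
*tracked* when the fit converged and confidence ≥ 0.75 (default). These two
constants are operating-point choices, not estimates of anything; both are
`estimator_config()` fields. Because this surrogate is computed from
reprojection residuals rather than from a learned landmark model's fit
likelihood, its numeric values are not comparable to any particular
commercial tracker's confidence display — only its semantics (monotone
degradation with fit quality) are.

## The synthetic-data generator

No public landmark-annotated video is bundled; everything is generated:

* `make_subject()` perturbs the canonical shape with seeded isotropic
  Gaussian noise (default 2 mm SD — the scale of adult facial-landmark
  variation) and rescales to a chosen true IPD, emulating inter-subject
  variation.
* `render_sequence()` projects a pose trajectory and applies the stressors
  that make real video hard: i.i.d. pixel noise, optional noise growing
  with pose eccentricity (`noise_gain_per_deg`, see below), random landmark
  occlusion, and whole dropped frames. Ground truth is recorded for every
  frame; all draws are seeded and bitwise-reproducible.
* `crom_protocol_poses()` enumerates the 43-target fixation protocol
  (yaw and pitch: 0, ±5 … ±40°, 17 targets each; roll: −40 … +40° by 10°,
  9 targets), and `simulate_protocol_study()` turns it into a paired
  two-instrument table: per subject × trial a *true executed* posture is
  drawn as target + Gaussian execution error (default SD 3° — subjects
  aim their heads at targets, they are not clamped to them), then each
  instrument reads that executed posture with its own noise (default SD 1°
  each). With 4 subjects this yields the 172-row layout (68 yaw, 68 pitch,
  36 roll observations).

Default geometry: subject 1.2 m from a 1920×1080 camera with focal length
1920 px.

What the generator does *not* emulate: landmark-detector failure modes that
are correlated across points (hair over the face, motion blur), rolling
shutter, lens distortion, soft-tissue deformation with expression, and any
systematic bias of a head-mounted comparator device. Passing tests on this
synthetic data therefore demonstrate that the *geometry and statistics* are
implemented correctly and behave sensibly under generic noise — they are
not a claim about accuracy on real video.

### Emulating degradation at extreme pose

Real trackers lose accuracy toward extreme postures, because landmark
localization degrades as the face turns away. The generator models this
with a per-frame noise SD of `noise_sd_px + noise_gain_per_deg × e`, where
e = max(|yaw|, |pitch|, |roll|) is the pose eccentricity. The
characterization analyses in this package use a base of 0.5 px and a gain
of 1.5 px/°, chosen so that the emulated error crosses the 5° clinical
accuracy threshold within a ±40° sweep — i.e. so the simulated tracker,
like real ones, has a finite operational range inside the tested extent.
These runs use a permissive estimator configuration
(`residual_scale = 0.5`, `confidence_threshold = 0.1`): the point of the
analysis is to *measure* the degraded frames, and the default operating
point would exclude most of them as untracked and mask the effect being
characterised.

## Evaluation machinery

`absolute_errors()` compares estimates to ground truth per frame with a
proper angular metric (differences wrapped into (−180, 180]); untracked
frames are kept in the table with NA errors and excluded-but-counted in
summaries, mirroring how a confident-recognition rate is reported
separately from accuracy. The per-frame **combined** error is the mean of
the three per-axis absolute errors, so the combined mean over frames equals
the grand mean of all per-axis errors (an identity the tests assert);
medians are reported alongside means because rare high-error frames (rapid
motion, occlusion) inflate means but would be ignored in clinical use.

`operational_range()` bins frames by each axis's true value (5° bins by
default, matching the protocol granularity) and returns the largest
symmetric ±L such that every populated bin inside it has mean combined
error below the threshold (5° default). The rule is monotone in the
threshold. `single_axis_subset()` (dominance threshold 10° by default:
"predominantly one axis" needs an operational definition, and 10° separates
the protocol's pure-axis sweeps cleanly) and `repeated_pose_icc_prep()`
build the pure-axis and repeated-pose subsets used for subanalysis and
reliability.

## Agreement statistics

For paired instrument series the package computes Pearson correlation
(p-value from the exact t transform with n − 2 degrees of freedom),
ordinary least squares of instrument B on instrument A (R² computed from
residual sums of squares; it equals r² algebraically, which the tests check
to 1e-12), and Bland–Altman analysis: differences d = B − A, bias =
mean(d), limits of agreement bias ± 1.96·SD(d) with the sample SD. The
1.96 multiplier gives nominal 95% limits for Gaussian differences; a
seeded 10,000-draw simulation in the test suite confirms coverage between
94% and 96%. `restrict_to_operational_range()` filters pairs on the
*comparator* instrument's reading — the reference should be the instrument
that is independent of the one under test.

The intraclass correlation (`icc()`) uses the classical two-way
random-effects mean-squares decomposition (rows = poses, columns =
repeats): ICC(2,1) for single measures and ICC(2,k) for average measures.
Absolute agreement is the default — for instrument reproducibility a
systematic offset between repeats *should* count against reliability — and
the consistency variant is available via `type = "consistency"`. The
implementation is verified to 1e-12 against a brute-force sum-of-squares
oracle and against `aov()` mean squares.

## Numerical choices and degenerate inputs

* Finite-difference steps: 1e-4° (angles) and 1e-2 mm (translation),
  central differences; small enough for quadratic convergence, large
  enough to stay clear of floating-point cancellation at 1e3-px scales.
* Rank deficiency of the visible-landmark configuration (all collinear) is
  detected via QR rank at initialization and surfaces as a degenerate-
  configuration error; `estimate_pose()` converts it to an untracked frame.
* Fully occluded frames, frames with fewer than 6 visible points, and
  unstructured (pure noise) frames return `tracked = FALSE` with NaN pose
  — never an exception — because per-frame failure is normal operation for
  a video tracker.
* Zero-variance series, constant regressors, incomplete ICC matrices and
  empty post-filter summaries are hard errors with named messages: in a
  clinical analysis a silently degenerate statistic is worse than a stop.
* Config files are a flat YAML mapping with unknown keys rejected by name,
  so a misspelled threshold cannot silently revert to a default.

## Problem sizes used in the shipped analyses

The test-suite and acceptance analyses use sizes chosen to make every
statistical check stable at desk scale: a 350-pose exact-recovery grid;
100 replicates per noise level in the σ ∈ {0.5, 1, 2, 4} px sweep; 10,000
draws for Bland–Altman coverage; 14 × 8 reliability matrices (the shape of
a realistic repeated-pose pitch subset); 4 × 43 = 172-row protocol
emulations; and 17-pose × 6-repeat eccentricity sweeps per axis. A full
acceptance run completes in well under a minute.

## Known limitations

* One rigid face shape: no identity-specific or deformable fitting, so
  estimates for faces far from average proportions carry a shape-induced
  bias (in synthetic experiments, ~2 mm landmark perturbation at 1.2 m
  costs well under a degree).
* Metric distance inherits the IPD assumption bias described above.
* No temporal smoothing: each frame is independent, which keeps the
  validation honest (errors are i.i.d. across frames) but leaves accuracy
  on the table for video use.
* Camera-relative pose only; torticollis measured against the trunk
  requires the camera-shoulder alignment assumption to hold.
* The confidence scale is a residual-based surrogate; thresholds
  transferred from other systems' confidence displays are not meaningful
  here.
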