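---
title: "Mirror-stereo reconstruction and kinematic analysis of skilled reaching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirror-stereo reconstruction and kinematic analysis of skilled reaching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrorreach)
```

## The problem

In the rat skilled-reaching task, the animal reaches through a narrow slot
to grasp a sugar pellet. A single high-speed camera (300 frames/s) views the
slot head-on, and an angled side mirror provides a second, virtual viewpoint
of the same scene. Markerless pose tracking yields per-frame 2D coordinates
with confidences for seven body parts (four digit tips, the paw dorsum, the
nose, and the pellet) in each view. `mirrorreach` turns those 2D tables into
3D reach-to-grasp kinematics and the session- and group-level statistics
used to detect effects of optogenetic dopamine manipulations, and ships a
seeded synthetic-data generator so the whole chain is testable without
video.

## Two-view geometry with a mirror

A planar mirror turns the single camera into a stereo pair: the mirror view
is what a "virtual" camera behind the mirror would see. The catch is that a
reflection is an improper transform — the virtual camera is left-handed —
while the essential-matrix machinery assumes proper rotations
(det R = +1). We therefore negate the mirror view's horizontal pixel
coordinate before any two-view computation (`mirror_flip`). Composing this
second reflection with the mirror reflection produces a proper virtual
camera whose intrinsics equal K with the principal point's x negated, after
which the textbook chain applies:

1. **Fundamental matrix** F from checkerboard-cube corner correspondences
   by the Hartley-normalized eight-point algorithm (least squares over all
   pairs; the corners are curated, so no robust loop is needed by default).
   Rank 2 is enforced by zeroing the smallest singular value.
2. **Essential matrix** E = K_mirror' F K, decomposed by SVD into four
   (R, t) candidates; the candidate placing the calibration corners in
   front of both cameras (cheirality) wins.
3. **Metric scale** from the first listed pair of adjacent checkerboard
   corners, whose physical spacing is the 4 mm square size; the remaining
   adjacency pairs serve as a consistency diagnostic (`scale_spread`).
4. **Triangulation** of confident label pairs by the linear midpoint
   method, vectorized over frames. The reprojection error of a point is
   the mean over the two views of the pixel distance between observed and
   reprojected labels.

The world frame is the direct camera frame (origin at the lens, z along the
optical axis), converted per trial to the analysis frame: origin at the
median pre-trigger pellet position, +z paw advancement past the pellet, +y
downward, +x lateral, with x negated for left-pawed sessions so all rats
are comparable.

On noiseless synthetic data this chain is exact to numerical precision
(< 1e-6 mm end to end); with 0.5 px label noise the trajectory RMSE on the
default rig is well under 0.2 mm. Both figures are recomputed by the test
suite and by `scripts/acceptance.R`.

## Quality control

Three defenses against tracking errors, in order:

* **Confidence gate** (`conf_min`, default 0.9): labels below threshold in
  either view are not triangulated. The threshold is not stated by tracking
  conventions; 0.9 is a common operating point and is configurable.
* **Reprojection filter** (`reproj_threshold_px`, default 3 px): a body
  part identified accurately in one view but misidentified in the other
  (e.g. two digits swapped) triangulates to a point that reprojects badly;
  such points are excluded. On synthetic digit-swap fixtures exactly the
  corrupted points exceed the threshold, because the noiseless background
  error is ~1e-11 px while a swap produces tens of pixels.
* **Gap bridging** (`max_gap` 5 frames, `tol_px` 3 px): a part missing in
  3D for a short stretch but confidently labelled in exactly one view is
  interpolated in time (monotone piecewise cubic per coordinate) and
  accepted only if the estimate reprojects within `tol_px` of the observed
  single-view label. Longer gaps stay missing.

## Reach segmentation

The second digit's advancement coordinate z_digit2 drives segmentation.
For each outward crossing of the slot plane (z = −15 mm; the pellet sits
15 mm beyond the slot):

* **Start**: walk backwards from the crossing while the paw dorsum moves
  forward; the reach starts at the frame after the last non-positive
  frame-to-frame dorsum step. The zero threshold avoids a free parameter.
* **End**: the frame at which z_digit2 attains its maximum before
  sustained retraction — the maximum reach extent. The raw series is
  boxcar-smoothed over `end_smooth = 3` frames for locating this maximum:
  near the endpoint the true curve is locally flat (the advance
  decelerates smoothly), so with realistic label noise the literal "first
  decreasing frame" rule fires early on a noise downtick; the short boxcar
  restores the intended frame while leaving noiseless data untouched
  (plateau ties resolve to the last plateau frame, since "began to
  retract" implies strict decrease). On 500 synthetic trials at 0.5 px
  noise, detected end frames land within ±2 frames of ground truth for
  ≥ 95% of reaches.
* A second reach requires full retraction below the slot plane first; how
  much retraction should reset the counter is not externally specified, and
  full retraction is the conservative choice.
* Candidate reaches advancing less than 2 mm beyond the slot or lasting
  under 3 frames are treated as jitter and dropped (both configurable).
* Trials that open with the paw already through the slot are flagged
  `paw_through_slot` and excluded from success-rate denominators.

## Kinematics and coordination profiles

Grasp aperture is the 3D distance between the first and fourth digit tips;
paw orientation is the angle of the digit1–digit4 line against the floor,
measured on the frontal (x–y) projection in [0°, 90°] (smaller = more
pronated). The verbal definition of the angle admits either the frontal
projection or the full 3D segment-to-plane angle; the frontal projection is
implemented because the angle is judged against the floor as seen head-on,
and the choice is isolated behind `orientation()`. Paw velocity divides
consecutive-frame dorsum displacements by 1/300 s, with no smoothing and no
bridging across gaps.

Coordination profiles re-parameterize the reach by advancement rather than
time: within a reach, frames are restricted to the maximal retained
strictly-increasing subsequence of z_digit2 (each retained frame exceeds
every previously retained value — a z-parameterized curve must be
single-valued, and this greedy rule handles non-monotone jitter without
discarding the reach), then each digit's coordinates are interpolated as
monotone piecewise-cubic (pchip) functions of z_digit2 and evaluated on the
fixed grid −20.0, −19.9, …, +15.0 mm (351 points). Aperture(z) and
orientation(z) derive from the interpolated digit tracks; grid points
outside a reach's observed z range are masked, and averages at a queried z
(+1 mm ordinarily; −7 mm for severely shortened reaches) include only the
reaches that cover it.

## The synthetic generator

The generator emulates the recorded structure of one trial: 1300 frames at
300 frames/s, 300 of them pre-trigger with the paw held behind the slot.
The paw advances along a minimum-jerk path (smooth, single-peaked velocity
— the standard model for point-to-point limb movements) to an endpoint
drawn from N(extent_mean, extent_sd), then retracts; digit tips are placed
around the cluster centre so that aperture and orientation follow logistic
profiles of z (aperture defaults (5, 14, −7, 2) mm; orientation
(90, 35, −8, 1.2) degrees — digits spread and the paw pronates as it
approaches the pellet). Defaults: extent 4 ± 1.5 mm, peak speed 350 mm/s,
values chosen as typical for rat reach-to-grasp at this scale. Projection
through the synthetic rig (focal length 3600 px for a 2400×1024 sensor
viewing a ~200 mm scene at ~300 mm — the field of view of the described
recording geometry) is degraded with isotropic pixel noise (0.5 px),
missing labels (2%), and digit-identity swaps confined to one view and one
frame (0.2%), the error mode reprojection filtering exists for.

Outcome codes 0–10 follow the task's scoring scheme, but are assigned
mechanistically by a grasp rule rather than by human inspection: a first
reach whose maximum extent lands in the grasp window [0, 6] mm with
aperture ≥ the 3 mm pellet diameter at the pellet is a first-try success
(1); short reaches leave the pellet in place (7), possibly captured on a
later attempt (2); overshoots or closed-paw contacts knock it off (4).
Neither the pellet diameter nor the grasp window is externally specified;
both are configurable placeholders. This rule makes success rates an
emergent consequence of programmed kinematic drift.

A default experiment has five groups (stimulation/inhibition during or
between reaches, plus control), six rats per group, and 22 analyzed
sessions (2 retraining + 10 laser + 10 occlusion) of 60 trials. Gradual
effect schedules accumulate parameter drifts across laser sessions of
"during" groups only (defaults: extent −2 mm/session, aperture midpoint
−0.5 mm/session, peak speed −25 mm·s⁻¹/session for stimulation; extent
+1 mm/session for inhibition); occlusion sessions revert the accumulated
drift immediately (`revert_rate = 1`), reflecting the observation that
kinematics return to baseline within the first occlusion session, and the
rate is configurable for persistence scenarios. Abrupt schedules alternate
the laser off/on every 5 trials with an immediate, non-accumulating effect.

`generate_experiment()` offers three detail levels: `summary` draws
per-trial kinematic endpoints directly from the programmed profiles (used
for session/group statistics, where only endpoint distributions matter and
the frames→pose→reconstruction fidelity is certified separately);
`frames` synthesizes full ground-truth trajectories; `pose` adds degraded
two-view tracking tables. What the generator does **not** emulate: real
tracking's correlated, heteroscedastic errors, pellet displacement after
contact, licking outcomes, posture-dependent occlusions, or abnormal
involuntary movements. Passing tests therefore certify the pipeline's
correctness and sensitivity under a known forward model, not performance
on real video.

## Session metrics and statistics

First-reach success is scores of 1 over attempted trials (scores 1, 2, 3,
4, 7); any-reach success uses {1, 2} in the numerator. Per-rat series are
normalized to the mean of the last two retraining sessions. Within-session
trends use trailing moving blocks of 10 trials, reported at the block's
last trial, with each rat's final value carried forward so group averages
are not distorted by dropout. Extent-matched comparisons stratify trials
into 1-mm bins of maximum extent starting at 0 mm (negative-extent trials
are tallied but not binned, as the bin scheme begins at zero).
Abnormal-involuntary-movement scores multiply amplitude by basic (duration)
per region, sum axial and limb composites into a global score, and take
contralateral minus ipsilateral full turns as rotational bias.

Mixed models are fit by REML via `lmerTest` with random intercepts per rat
(optionally correlated random slopes for laser, session, or trial within
block — the structure varies per analysis and is exposed in `lmm_spec()`
rather than fixed); per-coefficient t statistics and post hoc contrasts use
Satterthwaite approximate degrees of freedom, matching the fractional df
convention of behavioural reports. Normalized scores can contain zeros, so
the inverse hyperbolic sine (not the log) is applied before fitting when
requested. Trialwise group comparisons use Wilcoxon rank-sum tests at each
trial position with a raw p < 0.01 cutoff and deliberately no multiplicity
correction; exact p values are used where sample sizes permit. Sign tests,
Kruskal–Wallis tests, and paired t tests by extent bin round out the
toolkit.

## Numerical choices and degenerate inputs

* Eight-point estimation errors out when fewer than 8 pairs are given or
  when the normalized design matrix is rank-deficient (relative 8th
  singular value < 1e-9), which catches coplanar corner sets.
* Essential decomposition errors out if no candidate passes cheirality for
  at least 75% of the corners — the symptom of an uncorrected mirror
  handedness.
* Midpoint triangulation marks near-parallel ray pairs (2×2 determinant
  < 1e-12) as missing rather than returning huge coordinates.
* `profile_by_extent()` needs ≥ 4 usable frames on the advancing path;
  otherwise it returns an all-masked profile rather than extrapolating.
* End-of-reach aperture/orientation fall back to the nearest valid frame
  within 2 frames when tips are missing exactly at the end frame.
* Zero baselines make normalized series undefined (NA with a warning)
  rather than infinite.
* Sign tests on all-tied pairs are reported as undefined, not p = 1.

## Problem sizes used in validation

The test suite and acceptance script run entirely on synthetic data at
desk scale: single trials for geometric exactness; 500 trials at 0.5 px
noise for segmentation accuracy; 1000 randomized fixtures for the
arithmetic oracles; 30–40 reaches per condition for coordination-shift
recovery; 20 replicates of a 3-group × 6-rat × 22-session × 60-trial
experiment for gradual effect recovery; 20 replicates of 6-rat alternating
sessions for the abrupt analysis; 1000 null replicates for rank-sum
calibration and 100–200 for mixed-model CI coverage. These sizes give
Monte-Carlo error comfortably below the margins being tested.

## Known limitations

* One mirror view per reconstruction; the second side mirror and any
  multi-view fusion are out of scope, as are lens distortion and bundle
  adjustment.
* Intrinsics are supplied by configuration, not estimated.
* The pellet is not tracked after contact, and grasp closure/contact
  timing is not detected.
* Outcome codes for real data come from human scoring; only synthetic
  outcomes are machine-generated.
* The floor/axis orientation of the analysis frame comes from chamber
  configuration, not from the data.
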