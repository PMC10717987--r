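---
title: "Comparing marker sets for inverse-kinematic gait analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing marker sets for inverse-kinematic gait analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitkin)
```

## The problem

Optical gait analysis estimates lower-limb joint angles from skin-mounted
reflective markers. Two design choices define a *gait model*: the marker
protocol (which markers, where) and the segment-pose estimation algorithm.
`gaitkin` implements the inverse-kinematic (IK, "global optimization")
approach: a linked rigid-body model of the lower extremities is posed so
that its virtual markers match the measured ones in a weighted
least-squares sense. Because the chain is rigid, segment lengths stay
constant during walking — unlike direct (conventional) gait models, whose
apparent segment lengths can vary by centimetres.

The package supports two protocols on the same model:

* **Plugin (P-model)**: the standard 16-marker lower-body set — LASI, RASI,
  LPSI, RPSI on the pelvis and THI, KNE, TIB, ANK, HEE, TOE per side.
* **Redundant (R-model)**: the Plugin set plus 22 extra markers (11 per
  side): thigh and shank cluster extras (`*_A`, `*_P`, `*_I`), iliac crest
  (IC), medial femoral epicondyle (KNE_M), medial malleolus (ANK_M), 5th
  metatarsal (M5) and dorsal tarsal (T).

Adding markers makes the least-squares fit more robust to marker
misplacement, soft-tissue artifact (STA) and occlusion. The package's
pipeline quantifies this claim under controlled synthetic conditions, and
provides the statistics used to compare marker sets and subject groups.

A note on the extras: published descriptions of this redundant protocol
enumerate ten of the eleven per-side extra markers. The eleventh
implemented here is the medial malleolus (ANK_M), the standard medial
partner of KNE_M; its definition is isolated so it can be swapped.

## The model

The rigid-body chain has 9 segments (pelvis; femur, shank, talus, foot per
side) and 22 degrees of freedom: 6 at the pelvis (free joint), 3 per hip,
3 per knee, 1 per ankle (dorsi/plantarflexion) and 1 per subtalar joint
(inversion/eversion). The lab frame is right-handed with X the walking
direction and Z up; marker positions are in mm and all API-level angles in
degrees. Three-DOF joints apply an intrinsic Cardan sequence flexion →
adduction → internal rotation, with axes mirrored between sides so that
flexion, adduction, internal rotation, dorsiflexion and inversion are
positive on both sides. The zero pose is anatomical standing with straight
knees; joint centres sit on segment longitudinal axes scaled by the seven
length parameters (pelvic width; thigh, shank, foot length per side). The
talus is a massless intermediate segment of fixed nominal height (10 mm) —
only its two single-DOF joints matter.

The pose-vector layout is fixed and documented in `pose_names()`:
entries 1–3 pelvis translation (mm), 4–6 pelvis tilt/obliquity/rotation,
then 8 right-leg and 8 left-leg joint angles.

```{r}
m <- build_model()
n_dof(m)
head(pose_names(), 8)
```

## Calibration from a standing trial

Subject-specific scaling uses a quiet-standing reference trial:

1. **Scaling**: the seven segment lengths and the 22-entry static pose are
   fitted jointly by damped nonlinear least squares
   (Levenberg–Marquardt via `minpack.lm`), minimizing the squared
   distances between the time-averaged standing markers and the model's
   markers at their *nominal* (length-scaled) placements. Lengths are
   bounded to [0.5, 1.5] × nominal and angles to ±45°; the fit is
   deterministic. Standing frames are time-averaged per marker before
   fitting, which suppresses white marker noise.
2. **Offsets**: each marker's mean standing position is then expressed in
   its segment's fitted frame. By construction the calibrated model
   reproduces the standing means exactly at the static pose.

Observability is verified by the rank (SVD of a finite-difference
Jacobian) of the fitted problem; degenerate marker geometries are
rejected rather than silently fitted.

The two-arm comparison is *controlled*: the model is calibrated once with
the redundant protocol and the Plugin arm is derived by
`reduce_to_plugin()`, a pure filter. Shared markers keep bit-identical
offsets, and the Plugin arm's input data are the redundant data minus
exactly 22 columns, so any downstream difference is attributable to the
marker set alone.

```{r}
truth <- build_model()           # ground-truth subject
proto <- redundant_marker_set(truth)
standing <- generate_standing(truth, proto, white_sigma = 0, n_frames = 5)
cal_R <- calibrate(standing, proto)
cal_P <- reduce_to_plugin(cal_R)
round(cal_R$model$lengths, 2)
```

## Inverse kinematics

Each frame solves
\(\min_q \sum_i w_i \lVert m_i^{exp} - m_i^{model}(q)\rVert^2\)
over the 22-entry pose with Levenberg–Marquardt (cost tolerance
10⁻¹⁰ mm², at most 100 iterations per frame; weights default to 1 —
vendor weighting is unpublished, so uniform is the neutral choice, and
`ik_config()` exposes them). Occluded markers drop out of the objective
frame-by-frame; observability is re-checked whenever the occlusion
pattern changes, and an unobservable pose (e.g. all pelvis markers lost
with the 16-marker set) raises an error naming the weak DOFs rather than
returning garbage.

Numerical choices worth knowing:

* Pelvis translations are internally rescaled (mm → cm) so optimizer steps
  are commensurate with the degree-scaled angle entries.
* Each solve optimizes the *update* relative to the starting pose in short
  re-centred chunks, so the trust-region machinery behaves identically for
  cold starts at the origin and warm starts mid-walkway; iteration stops
  on the solver's own convergence tests, on a scale-free gradient
  criterion at the noise floor, or when a chunk no longer reduces the
  cost.
* Trajectories are solved with warm starts (frame *t* starts at the
  solution of *t* − 1, frame 1 at the calibration pose) and angles are
  unwrapped along the way.
* Cardan parameterizations are not unique: the solver canonicalizes each
  solution (angles wrapped to (−180°, 180°], the middle angle of each
  3-DOF joint in [−90°, 90°]), which fixes the alias
  (f, a, r) ≡ (f+180°, 180°−a, r+180°) without changing the rotation.
* From a cold start far from the solution LM can stall in a local
  minimum; if the residual RMS exceeds a threshold (1 mm cold;
  along a trajectory, twice the previous frame's residual) a small fixed
  set of alternative initial poses is tried and the best kept. This is
  deterministic — there are no random restarts.

With noiseless synthetic data the FK → IK round trip recovers poses to
better than 10⁻⁴ degrees, which is the package's primary correctness
oracle.

## Gait processing

Cycles are the intervals between adjacent right-leg heel strikes. When
force-platform events are unavailable, strikes are detected at local
maxima of the heel's anteroposterior position relative to the pelvis
(coordinate-based rule; annotated events always take precedence; peaks
closer than 0.4 s are merged). Each angle is resampled onto 101 points
(0–100 % of the cycle) by natural cubic splines without smoothing. Per
curve, four kinematic variables are extracted: initial angle (value at
heel strike), peak maximum, peak minimum, and range of motion. The
intra-subject variability statistic is the **mean absolute variability**:

\[ \mathrm{MAV} = \frac{1}{101}\sum_{k=0}^{100}
   \left[\max_{trial} \theta_k - \min_{trial} \theta_k\right] \]

a per-point across-trial range averaged over the cycle; a single trial
gives 0 by definition. Cycles with occlusion-induced gaps in the solved
angles are excluded rather than imputed.

## Statistics

The comparison layer mirrors standard gait-lab practice: Shapiro–Wilk
normality checks, paired *t*-tests for between-model differences (the
same subjects under both marker sets) and for MAV, independent *t*-tests
(pooled by default; Welch available) for between-group differences, and a
point-wise paired comparison at each of the 101 cycle points with an
uncorrected significance count at α = 0.05. No multiple-comparison
correction is applied by default — the point-count is reported raw, as is
conventional in this literature — but `pointwise_compare(adjust =)`
accepts any `p.adjust` method for more conservative reuse. Normality
failures warn rather than silently switching to nonparametric tests.
Tests are two-sided by default.

`power_n_two_sample()` performs the a priori sample-size search for the
independent two-sample *t*-test from the noncentral *t* distribution. At
effect size d = 1.37, α = 0.05 and target power 0.80 the one-tailed
computation gives a smallest total N of 16 (power 0.831; N = 14 gives
0.779), while the two-tailed variant needs 20 — reproducing published
G*Power-style sample sizes of 16 therefore requires `tails = 1`.

```{r}
power_n_two_sample(1.37, alpha = 0.05, power = 0.80, tails = 1)
```

## The synthetic gait generator

No public motion data accompany this problem, so every stage is validated
by parameter recovery on synthetic trials with known ground truth:

* **Trajectories**: stride-periodic Fourier series per angle (mean + up to
  4 harmonics), pelvis translating at constant speed (default 1.2 m/s,
  stride 1.1 s, 100 Hz sampling). Defaults are cosine-only, so every angle
  is an even function of cycle phase about the heel strike; the
  heel-forward peak then falls exactly on the stride boundary and the
  coordinate-based event rule is exact on noiseless data. Default ranges
  resemble normal level walking (hip flexion ≈ −10…30°, knee flexion
  ≈ 5…59°).
* **Soft-tissue artifact**: per marker coordinate, a stride-periodic
  sinusoid with random phase, scaled by segment-dependent weights
  (femur 1.0, shank 0.7, pelvis 0.5, foot 0.3 — thigh markers move most,
  consistent with the STA literature), plus isotropic white noise.
* **Misplacement and occlusion**: constant per-marker offset vectors
  (misplacement relative to calibration) and frame-window masks.
* **Determinism**: a seed makes generation bit-for-bit reproducible.

What the generator does *not* emulate: contact mechanics and ground
reaction (heel-strike truth is defined at stride boundaries of the
parameterization), realistic autocorrelated marker dropout, non-periodic
stride-to-stride variability, and subject-specific STA fields. Passing
tests therefore demonstrate correctness of the estimation machinery and
the *direction* of marker-set effects under controlled noise — not
clinical equivalence on real data.

## Robustness experiment and study conditions

`run_robustness_experiment()` operationalizes the redundancy claim: per
seed it calibrates both arms from a noisy standing trial, solves identical
walking trials, and measures per-angle RMSE against truth. The packaged
study conditions (also used by the acceptance tests) are: 20 seeds, 3
trials per synthetic subject, 3 strides at 50 Hz per trial, STA amplitude
5 mm with 1 mm white standing noise. Under these conditions the redundant
arm's median angle RMSE and median per-subject MAV are at or below the
plugin arm's — the synthetic analogue of the reported finding that the
redundant set shows less intra-subject variation.

```{r, eval = FALSE}
res <- run_robustness_experiment(
  scenarios = list(sta5 = noise_config(sta_amplitude = 5)),
  seeds = 1:20)
summarize_robustness(res)
```

## Known limitations

* Exact numeric agreement with any specific commercial implementation
  (segment frame conventions, internal Euler sequences, marker weights) is
  not claimed; those conventions are unpublished.
* Nominal marker placements are geometric defaults on a scaled template;
  real palpation error is handled through calibration, not modelled in the
  placements themselves.
* The pipeline averages a subject's trials before group statistics
  (standard practice); pooling trials instead would change the effective
  sample size of the group tests.
* No joint limits are imposed during solving; an optional bounds flag is
  deliberately left out of the default path to match the unconstrained
  least-squares objective.
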