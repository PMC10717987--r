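# gaitkin

Marker-based gait kinematics via inverse kinematics, built to compare
marker protocols on a common rigid-body model.

## What it is for

Clinical and research gait labs estimate lower-limb joint angles from
optical markers. With the inverse-kinematic (IK) approach, a linked
rigid-body model is posed frame-by-frame so its virtual markers match the
measured ones in a weighted least-squares sense:

    q* = argmin_q  Σᵢ wᵢ ‖ mᵢ_exp − mᵢ_model(q) ‖²

`gaitkin` implements a 22-DOF lower-extremity model (6-DOF pelvis, 3-DOF
hips and knees, 1-DOF ankles and subtalar joints; 9 segments), two marker
protocols on that model — the standard 16-marker **Plugin** set and a
38-marker **Redundant** set (Plugin + 22 extras, 11 per side) — and the
full analysis chain used to compare them:

* standing-trial calibration (segment-length scaling + per-marker offsets
  by nonlinear least squares),
* trajectory IK with warm starts, occlusion handling and observability
  (Jacobian-rank) checks,
* gait-cycle segmentation, 101-point time normalization, kinematic
  variables (initial angle, peaks, ROM) and the mean absolute variability
  statistic MAV = mean over the cycle of the per-point across-trial range,
* a statistics layer (Shapiro–Wilk, paired and independent *t*-tests,
  point-wise significance counts, noncentral-*t* sample-size search),
* a synthetic gait generator with exact ground truth (soft-tissue
  artifact, marker misplacement, occlusion), so every stage is testable by
  parameter recovery,
* TRC marker-file I/O and a two-arm comparison pipeline
  (`run_pipeline()`), in which the Plugin arm is derived from the
  Redundant calibration by pure reduction — identical offsets for shared
  markers, identical data minus 22 columns — so observed differences are
  attributable to the marker set alone.

See the vignette (`vignettes/gait-marker-sets.Rmd`) for the model
conventions, numerical choices and the limits of what the synthetic
evidence shows.

## Worked example

Calibrate a synthetic subject, solve one walking trial with both marker
sets, and extract right-knee sagittal kinematics:

```r
library(gaitkin)

subject  <- build_model(c(pelvic_width = 252, thigh_L = 408, thigh_R = 415,
                          shank_L = 398, shank_R = 394,
                          foot_L = 248, foot_R = 250))
protocol <- redundant_marker_set(subject)
standing <- generate_standing(subject, protocol, white_sigma = 1,
                              n_frames = 100, seed = 2)
cal_R <- calibrate(standing, redundant_marker_set(), build_model())
cal_R
#> calibrated_model (redundant protocol, 38 markers)
#> scaling residual rms: 0.09773 mm
#> pelvic_width      thigh_L      thigh_R      shank_L      shank_R       foot_L
#>        252.1        408.0        415.0        397.9        394.1        247.7
#>       foot_R
#>        249.9
```

The seven true segment lengths are recovered to within half a millimetre
from a 1 mm-noise standing trial. Now a walking trial with 5 mm
soft-tissue artifact, solved with both arms on identical data:

```r
trial    <- generate_trial(subject, protocol,
                           gait_trajectory_config(n_strides = 3, sample_rate = 50),
                           noise_config(sta_amplitude = 5, seed = 3))
angles_R <- solve_trajectory(cal_R, trial$markers)
angles_P <- solve_trajectory(reduce_to_plugin(cal_R),
                             reduce_to_plugin(trial$markers))

cycle   <- c(1.1, 2.2)   # one gait cycle, right heel strike to heel strike
curve_R <- time_normalize(angles_R, cycle, "knee_flexion_R")
curve_P <- time_normalize(angles_P, cycle, "knee_flexion_R")
rbind(R = unlist(extract_variables(curve_R$knee_flexion_R)),
      P = unlist(extract_variables(curve_P$knee_flexion_R)))
#>   initial_angle peak_max peak_min   rom
#> R          3.90    58.83     3.90 54.93
#> P          3.21    59.51     3.11 56.41
```

Against the generator's known truth, the redundant arm tracks the knee
curve about three times more accurately under this artifact level
(RMSE 0.52° vs 1.48°) — the redundancy pays for itself exactly where the
least-squares fit has to average out soft-tissue motion.

The a priori sample-size computation for an independent two-sample
*t*-test at effect size d = 1.37, α = 0.05 (one-tailed), power 0.80:

```r
power_n_two_sample(1.37, alpha = 0.05, power = 0.80, tails = 1)
#> [1] 16
```

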