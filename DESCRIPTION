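Package: gaitkin
Title: Marker-Based Gait Kinematics via Inverse Kinematics with Plugin and
    Redundant Marker Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lower-extremity rigid-body gait model (22 degrees of freedom)
    driven by global least-squares inverse kinematics from optical marker
    trajectories.  Implements the 16-marker Plugin and 38-marker Redundant
    protocols, standing-trial calibration (segment-length scaling and
    per-marker offsets), gait-cycle segmentation and 101-point time
    normalization, kinematic-variable extraction, the mean absolute
    variability (MAV) statistic, and the statistical layer used to compare
    marker sets and subject groups.  A synthetic gait generator with known
    ground truth (soft-tissue artifact, marker misplacement, occlusion)
    makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
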