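Package: mirrorreach
Title: Mirror-Stereo 3D Reconstruction and Kinematic Analysis of Rodent Skilled Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for markerless pose tracking of the rat
    skilled-reaching (pellet retrieval) task recorded with a single high-speed
    camera and a side mirror. Calibrates the direct/mirror two-view geometry
    from checkerboard-cube correspondences (normalized eight-point fundamental
    estimate, essential-matrix decomposition with mirror handedness
    correction), triangulates per-frame 2D body-part labels into 3D paw and
    digit trajectories, filters by reprojection error, segments trials into
    discrete reaches, and computes reach-to-grasp kinematics: maximum reach
    extent, grasp aperture, paw orientation, velocity, and coordination
    profiles re-parameterized on a paw-advancement grid by monotone piecewise
    cubic interpolation. Session- and group-level measures (success rates,
    baseline normalization, moving-block averages with carry-forward,
    extent-matched stratification, abnormal-involuntary-movement composites)
    feed linear mixed-effects models and nonparametric tests for detecting
    effects of optogenetic dopamine manipulations. A seeded synthetic-data
    generator produces ground-truthed experiments (camera rig, reach forward
    model, tracking noise, outcome codes, laser schedules) so every stage is
    testable without raw video.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
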