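# Shared fixtures, built once per test run: the default synthetic rig and a
# camera pair calibrated from noiseless checkerboard-cube corners.

.fx <- new.env()

default_rig <- function() {
  if (is.null(.fx$rig)) .fx$rig <- make_camera_rig()
  .fx$rig
}

default_pair <- function() {
  if (is.null(.fx$pair)) {
    rig <- default_rig()
    corr <- generate_calibration_set(rig, square_size_mm = 4)
    .fx$pair <- calibrate_camera_pair(corr, rig$K, square_size_mm = 4)
  }
  .fx$pair
}

# Ground-truth relative pose of the flipped virtual camera for a rig whose
# direct camera sits at the world origin: R = S H, t = S h with
# S = diag(-1, 1, 1) (the pixel u-flip expressed in camera coordinates).
true_relative_pose <- function(rig) {
  S <- diag(c(-1, 1, 1))
  list(R = S %*% rig$reflect_H, t = drop(S %*% rig$reflect_h))
}

# Noise-free pose series for a simulated reach.
clean_pose <- function(gt, rig = default_rig()) {
  project_and_degrade(gt, rig,
                      noise_cfg = list(px_sd = 0, p_missing = 0,
                                       p_mislabel = 0),
                      seed = 1)
}

# Maximum absolute 3D deviation between a reconstructed trajectory (pellet
# frame) and the generator's ground truth.
max_gt_error <- function(traj, gt, parts = bodypart_names()) {
  max(vapply(parts, function(bp) {
    tr <- part_track(traj, bp)
    max(abs(tr$xyz - gt$parts[[bp]]), na.rm = TRUE)
  }, 0))
}
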