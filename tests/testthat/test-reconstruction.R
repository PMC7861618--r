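# Triangulation, reprojection filtering, gap estimation, pellet frame.

test_that("noiseless reconstruction recovers ground truth to < 1e-6 mm", {
  pair <- default_pair()
  gt <- simulate_reach(reach_gen_params(), seed = 12)
  traj <- reconstruct_trajectory(clean_pose(gt), pair)
  expect_lt(max_gt_error(traj, gt), 1e-6)
})

test_that("a label missing in one view yields provenance missing", {
  pair <- default_pair()
  gt <- simulate_reach(reach_gen_params(), seed = 13)
  pose <- clean_pose(gt)
  # drop the mirror label of digit3 at frame 500
  i <- pose$mirror$bodypart == "digit3" & pose$mirror$frame == 500
  pose$mirror$confidence[i] <- 0.1
  fr <- triangulate_series(pose, pair)
  row <- fr[fr$bodypart == "digit3" & fr$frame == 500, ]
  expect_equal(row$provenance, "missing")
  expect_true(is.na(row$x))
})

test_that("swapped digit identities produce large reprojection errors", {
  pair <- default_pair()
  gt <- simulate_reach(reach_gen_params(), seed = 14)
  pose <- clean_pose(gt)
  ps <- project_and_degrade(gt, default_rig(),
                            noise_cfg = list(px_sd = 0, p_missing = 0,
                                             p_mislabel = 0.01),
                            seed = 15)
  expect_gt(length(ps$mislabel_log), 0)
  fr <- triangulate_series(ps, pair)
  swapped <- do.call(rbind, lapply(ps$mislabel_log, function(l) {
    data.frame(frame = l$frame, bodypart = l$parts)
  }))
  key <- paste(fr$frame, fr$bodypart)
  bad <- key %in% paste(swapped$frame, swapped$bodypart)
  expect_true(all(fr$reproj_err_px[bad] > 5))
  expect_lt(max(fr$reproj_err_px[!bad], na.rm = TRUE), 1e-9)
})

test_that("reprojection filtering removes exactly the corrupted points", {
  pair <- default_pair()
  gt <- simulate_reach(reach_gen_params(), seed = 14)
  ps <- project_and_degrade(gt, default_rig(),
                            noise_cfg = list(px_sd = 0, p_missing = 0,
                                             p_mislabel = 0.01),
                            seed = 15)
  fr <- triangulate_series(ps, pair)
  # all below threshold: identity
  clean <- triangulate_series(clean_pose(gt), pair)
  same <- filter_by_reprojection(clean, 3)
  expect_equal(attr(same, "n_removed"), 0)
  expect_identical(same$provenance, clean$provenance)
  # corrupted fixture: exactly the swapped points go
  filt <- filter_by_reprojection(fr, 3)
  swapped <- do.call(rbind, lapply(ps$mislabel_log, function(l) {
    data.frame(frame = l$frame, bodypart = l$parts)
  }))
  removed <- filt$provenance == "missing" & fr$provenance == "triangulated"
  expect_setequal(paste(filt$frame[removed], filt$bodypart[removed]),
                  paste(swapped$frame, swapped$bodypart))
  # near-zero threshold with noise removes everything triangulated
  noisy <- project_and_degrade(gt, default_rig(),
                               noise_cfg = list(px_sd = 0.5, p_missing = 0,
                                                p_mislabel = 0),
                               seed = 16)
  frn <- triangulate_series(noisy, pair)
  all_gone <- filter_by_reprojection(frn, 1e-9)
  expect_true(all(all_gone$provenance == "missing"))
})

test_that("one-frame gaps in smooth motion are estimated near-exactly", {
  pair <- default_pair()
  gt <- simulate_reach(reach_gen_params(), seed = 17)
  pose <- clean_pose(gt)
  # hide digit2's mirror label during the advance (frame 320)
  i <- pose$mirror$bodypart == "digit2" & pose$mirror$frame == 320
  pose$mirror$confidence[i] <- 0
  fr <- triangulate_series(pose, pair)
  est <- estimate_missing_points(fr, pose, pair)
  row <- est[est$bodypart == "digit2" & est$frame == 320, ]
  expect_equal(row$provenance, "estimated")
  truth <- drop(pellet_to_camera(matrix(gt$parts$digit2[321, ], 1),
                                 default_rig()))
  expect_lt(max(abs(c(row$x, row$y, row$z) - truth)), 5e-3)
})

test_that("gap estimates are exact for linear 3D motion", {
  pair <- default_pair()
  n <- 60
  tau <- (0:(n - 1)) / (n - 1)
  lin <- function(a, b) outer(rep(1, n), a) + outer(tau, b)
  parts <- list(digit1 = lin(c(-3, 1, -20), c(2, -1, 24)),
                digit2 = lin(c(-1, 0, -20), c(1, -1, 25)),
                digit3 = lin(c(1, 0, -20), c(0, -1, 25)),
                digit4 = lin(c(3, 1, -20), c(-2, -1, 24)),
                pawdorsum = lin(c(0, 4, -28), c(0, -1, 25)),
                nose = lin(c(0, -6, -17), c(0, 0, 0)),
                pellet = lin(c(0, 0, 0), c(0, 0, 0)))
  gt <- structure(list(parts = parts), class = "gt_reach")
  pose <- clean_pose(gt)
  i <- pose$mirror$bodypart == "digit2" & pose$mirror$frame == 30
  pose$mirror$confidence[i] <- 0
  fr <- triangulate_series(pose, pair)
  est <- estimate_missing_points(fr, pose, pair)
  row <- est[est$bodypart == "digit2" & est$frame == 30, ]
  expect_equal(row$provenance, "estimated")
  truth <- drop(pellet_to_camera(matrix(parts$digit2[31, ], 1),
                                 default_rig()))
  expect_lt(max(abs(c(row$x, row$y, row$z) - truth)), 1e-6)
})

test_that("gaps longer than max_gap stay missing", {
  pair <- default_pair()
  gt <- simulate_reach(reach_gen_params(), seed = 18)
  pose <- clean_pose(gt)
  i <- pose$mirror$bodypart == "digit2" & pose$mirror$frame %in% 320:331
  pose$mirror$confidence[i] <- 0
  fr <- triangulate_series(pose, pair)
  est <- estimate_missing_points(fr, pose, pair, max_gap = 5)
  rows <- est[est$bodypart == "digit2" & est$frame %in% 320:331, ]
  expect_true(all(rows$provenance == "missing"))
})

test_that("estimates violating the observed-view tolerance are rejected", {
  pair <- default_pair()
  gt <- simulate_reach(reach_gen_params(), seed = 19)
  pose <- clean_pose(gt)
  i <- which(pose$mirror$bodypart == "digit2" & pose$mirror$frame == 320)
  pose$mirror$confidence[i] <- 0
  # the direct-view label jumps away: interpolation cannot match it
  j <- which(pose$direct$bodypart == "digit2" & pose$direct$frame == 320)
  pose$direct$u[j] <- pose$direct$u[j] + 40
  fr <- triangulate_series(pose, pair)
  est <- estimate_missing_points(fr, pose, pair, tol_px = 3)
  row <- est[est$bodypart == "digit2" & est$frame == 320, ]
  expect_equal(row$provenance, "missing")
})

test_that("pellet frame is centred, side-aware, and rigid", {
  pair <- default_pair()
  gt <- simulate_reach(reach_gen_params(), seed = 20)
  fr <- triangulate_series(clean_pose(gt), pair)
  right <- to_pellet_frame(fr, "right")
  pel <- part_track(right, "pellet")
  pre <- pel$frame >= 200 & pel$frame < 300
  expect_lt(max(abs(apply(pel$xyz[pre, ], 2, median))), 1e-9)
  # left-paw sessions flip x only
  left <- to_pellet_frame(fr, "left")
  for (bp in c("digit1", "pawdorsum")) {
    r <- part_track(right, bp)$xyz
    l <- part_track(left, bp)$xyz
    expect_equal(l[, 1], -r[, 1], tolerance = 1e-12)
    expect_equal(l[, 2:3], r[, 2:3], tolerance = 1e-12)
  }
  # rigid: inter-part distances preserved by the frame change
  f500 <- fr[fr$frame == 500, ]
  r500 <- right[right$frame == 500, ]
  d_cam <- dist(cbind(f500$x, f500$y, f500$z))
  d_pel <- dist(cbind(r500$x, r500$y, r500$z))
  expect_lt(max(abs(d_cam - d_pel)), 1e-9)
  # pellet never tracked: error
  nop <- fr[fr$bodypart != "pellet", ]
  expect_error(to_pellet_frame(nop, "right"), "pellet")
})

test_that("trajectory error grows monotonically with label noise", {
  pair <- default_pair()
  gt <- simulate_reach(reach_gen_params(), seed = 22)
  rmse <- vapply(c(0.1, 0.5, 1.5), function(sd) {
    pose <- project_and_degrade(gt, default_rig(),
                                noise_cfg = list(px_sd = sd, p_missing = 0,
                                                 p_mislabel = 0),
                                seed = 23)
    fr <- triangulate_series(pose, pair)
    traj <- to_pellet_frame(fr, "right")
    errs <- unlist(lapply(c("digit2", "pawdorsum"), function(bp) {
      rowSums((part_track(traj, bp)$xyz - gt$parts[[bp]])^2)
    }))
    sqrt(mean(errs, na.rm = TRUE))
  }, 0)
  expect_true(all(diff(rmse) > 0))
})
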