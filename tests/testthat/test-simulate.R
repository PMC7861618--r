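# Synthetic reach generator, tracking degradation, calibration-set builder,
# and the experiment-level generator.

test_that("endpoint and profile values hold by construction", {
  p <- reach_gen_params(extent_mean = 3, extent_sd = 0)
  gt <- simulate_reach(p, seed = 1)
  expect_equal(max(gt$parts$digit2[, 3]), 3, tolerance = 1e-12)
  expect_equal(gt$max_extent, 3, tolerance = 1e-12)
  # ground-truth aperture follows the logistic profile of z exactly:
  # at the frame nearest z = -7 (the midpoint), digit1-digit4 distance
  # equals (5 + 14)/2 = 9.5 by the logistic midpoint property
  ap <- sqrt(rowSums((gt$parts$digit1 - gt$parts$digit4)^2))
  z <- gt$parts$digit2[, 3]
  expect_equal(ap, logistic_profile(z, 5, 14, -7, 2), tolerance = 1e-9)
  expect_equal(logistic_profile(-7, 5, 14, -7, 2), 9.5)
  # paw held behind the slot for the 300 pre-trigger frames
  expect_true(all(z[1:300] < -15))
})

test_that("identical seeds reproduce identical trajectories", {
  p <- reach_gen_params()
  a <- simulate_reach(p, seed = 99)
  b <- simulate_reach(p, seed = 99)
  expect_identical(a, b)
  rig <- default_rig()
  pa <- project_and_degrade(a, rig, seed = 7)
  pb <- project_and_degrade(b, rig, seed = 7)
  expect_identical(pa, pb)
})

test_that("parameter validation rejects bad inputs", {
  expect_error(reach_gen_params(aperture_profile = c(10, 5, -7, 2)), "a_min")
  expect_error(reach_gen_params(n_frames = 3), "n_frames")
  expect_error(reach_gen_params(extent_sd = -1), "extent_sd")
})

test_that("pixel noise has the configured standard deviation", {
  rig <- default_rig()
  gt <- simulate_reach(reach_gen_params(), seed = 3)
  clean <- clean_pose(gt, rig)
  noisy <- project_and_degrade(gt, rig,
                               noise_cfg = list(px_sd = 0.5, p_missing = 0,
                                                p_mislabel = 0),
                               seed = 5)
  resid <- c(noisy$direct$u - clean$direct$u,
             noisy$direct$v - clean$direct$v,
             noisy$mirror$u - clean$mirror$u,
             noisy$mirror$v - clean$mirror$v)
  expect_gt(length(resid), 10000)
  expect_lt(abs(sd(resid) - 0.5) / 0.5, 0.05)
})

test_that("p_missing = 1 drives every confidence below threshold", {
  rig <- default_rig()
  gt <- simulate_reach(reach_gen_params(), seed = 3)
  pose <- project_and_degrade(gt, rig,
                              noise_cfg = list(px_sd = 0, p_missing = 1,
                                               p_mislabel = 0),
                              seed = 5)
  expect_true(all(pose$direct$confidence < 0.9))
  expect_true(all(pose$mirror$confidence < 0.9))
})

test_that("noiseless degradation round-trips through triangulation", {
  pair <- default_pair()
  gt <- simulate_reach(reach_gen_params(), seed = 8)
  fr <- triangulate_series(clean_pose(gt), pair)
  expect_lt(max(fr$reproj_err_px, na.rm = TRUE), 1e-9)
})

test_that("calibration cube has the advertised metric structure", {
  rig <- default_rig()
  corr <- generate_calibration_set(rig, square_size_mm = 4)
  expect_gte(nrow(corr$points), 20)
  d <- sqrt(rowSums((corr$X_true[corr$adjacency[, 1], ] -
                     corr$X_true[corr$adjacency[, 2], ])^2))
  expect_equal(d, rep(4, length(d)), tolerance = 1e-12)
  # corners span three dimensions (faces are not coplanar)
  Xc <- scale(corr$X_true, scale = FALSE)
  expect_equal(qr(Xc)$rank, 3)
  expect_error(generate_calibration_set(rig, square_size_mm = -4), "positive")
})

test_that("control schedules drift nothing and gradual drift is monotone", {
  des <- experiment_design(groups = c("stim_during", "control"),
                           rats_per_group = 1, trials_per_session = 200)
  exp1 <- generate_experiment(des, seed = 21)
  tt <- exp1$trials
  by_sess <- function(g) {
    s <- tt[tt$group == g & tt$stage == "laser_on", ]
    tapply(s$max_extent_mm, s$session, mean)
  }
  ctrl <- by_sess("control")
  base <- mean(tt$max_extent_mm[tt$group == "control" &
                                  tt$stage == "retraining"])
  # control: session means stay within noise of baseline (se ~ 0.11 mm)
  expect_lt(max(abs(ctrl - base)), 0.5)
  # stim-during: strictly decreasing session means under -2 mm/session
  stim <- by_sess("stim_during")
  expect_true(all(diff(stim) < 0))
})

test_that("abrupt blocks alternate off/on in runs of exactly block_length", {
  alt <- generate_alternating_sessions(n_rats = 2, trials_per_session = 60,
                                       block_length = 5, seed = 4)
  one <- alt[alt$rat == "r01", ]
  r <- rle(one$laser)
  expect_true(all(r$lengths == 5))
  expect_equal(r$values[1:4], c(0, 1, 0, 1))
})

test_that("unknown group labels are rejected", {
  expect_error(experiment_design(groups = c("control", "mystery")),
               "unknown group")
})

test_that("laser epochs follow the group timing rules", {
  des <- experiment_design(groups = c("stim_during", "stim_between"),
                           rats_per_group = 1, trials_per_session = 4,
                           n_retraining = 1, n_laser = 1, n_occlusion = 0)
  exp1 <- generate_experiment(des, seed = 31, detail = "frames")
  stages <- vapply(exp1$sessions, function(s) s$stage, "")
  grps <- vapply(exp1$sessions, function(s) s$manifest$group, "")
  las <- exp1$sessions[stages == "laser_on"]
  for (s in las) {
    ep <- s$laser_epochs[[1]]
    if (s$manifest$group == "stim_during") {
      expect_equal(unname(ep[c("start", "end")]), c(0, 1200))
    } else {
      expect_equal(unname(ep[c("start", "end")]), c(1500, 3000))
    }
  }
  expect_setequal(unique(grps), c("stim_during", "stim_between"))
})
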