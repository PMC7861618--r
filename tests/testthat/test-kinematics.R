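# Kinematic measures: aperture, orientation, speed, extent profiles.

frame_df <- function(parts_xyz, frame = 0) {
  do.call(rbind, lapply(names(parts_xyz), function(bp) {
    p <- parts_xyz[[bp]]
    data.frame(frame = frame, bodypart = bp, x = p[1], y = p[2], z = p[3],
               reproj_err_px = 0, provenance = "triangulated")
  }))
}

test_that("aperture is the digit1-digit4 Euclidean distance", {
  fr <- frame_df(list(digit1 = c(-2, 0, 5), digit4 = c(2, 0, 5)))
  expect_equal(aperture(fr)$aperture_mm, 4)
  fr0 <- frame_df(list(digit1 = c(1, 2, 3), digit4 = c(1, 2, 3)))
  expect_equal(aperture(fr0)$aperture_mm, 0)
  # missing tip propagates NA
  frm <- frame_df(list(digit1 = c(-2, 0, 5), digit4 = c(2, 0, 5)))
  frm$provenance[frm$bodypart == "digit4"] <- "missing"
  expect_true(is.na(aperture(frm)$aperture_mm))
})

test_that("aperture is invariant under the pellet-frame rigid transform", {
  pair <- default_pair()
  gt <- simulate_reach(reach_gen_params(), seed = 41)
  fr <- triangulate_series(clean_pose(gt), pair)
  traj <- to_pellet_frame(fr, "right")
  a_cam <- aperture(fr)$aperture_mm
  a_pel <- aperture(traj)$aperture_mm
  expect_equal(a_cam, a_pel, tolerance = 1e-9)
})

test_that("orientation measures the digit line against the horizontal", {
  flat <- frame_df(list(digit1 = c(0, 0, 5), digit4 = c(4, 0, 5)))
  expect_equal(orientation(flat)$orientation_deg, 0)
  vert <- frame_df(list(digit1 = c(0, 0, 5), digit4 = c(0, -4, 5)))
  expect_equal(orientation(vert)$orientation_deg, 90)
  mid <- frame_df(list(digit1 = c(0, 0, 5), digit4 = c(3, -3, 5)))
  expect_equal(orientation(mid)$orientation_deg, 45)
  # mirror-symmetric left-paw twin (x negated) has identical angle
  twin <- frame_df(list(digit1 = c(0, 0, 5), digit4 = c(-3, -3, 5)))
  expect_equal(orientation(twin)$orientation_deg, 45)
  # coincident projection undefined
  deg <- frame_df(list(digit1 = c(1, 1, 2), digit4 = c(1, 1, 9)))
  expect_true(is.na(orientation(deg)$orientation_deg))
})

test_that("speed uses the 1/300 s inter-frame interval", {
  z <- seq(0, 9)            # 1 mm per frame
  df <- data.frame(frame = seq_along(z) - 1, bodypart = "pawdorsum",
                   x = 0, y = 0, z = z, reproj_err_px = 0,
                   provenance = "triangulated")
  sp <- speed_series(df)
  expect_true(all(is.na(sp$speed_mm_s[1])))
  expect_equal(sp$speed_mm_s[-1], rep(300, 9))
  # stationary part has zero speed
  df$z <- 0
  expect_equal(speed_series(df)$speed_mm_s[-1], rep(0, 9))
  # gaps break the series
  df$z <- z
  df$provenance[5] <- "missing"
  sp <- speed_series(df)
  expect_true(all(is.na(sp$speed_mm_s[5:6])))
})

test_that("the advancement grid has 351 points at 0.1 mm spacing", {
  g <- extent_grid()
  expect_length(g, 351)
  expect_equal(g[1], -20)
  expect_equal(g[351], 15)
  expect_equal(unique(round(diff(g), 12)), 0.1)
})

test_that("profiles reproduce linear digit tracks exactly and mask range", {
  # digits move linearly in z_digit2: pchip reproduces linear data
  n <- 40
  z2 <- seq(-12, 3, length.out = n)
  mk <- function(bp, x0, dx) data.frame(frame = seq_len(n) - 1, bodypart = bp,
                                        x = x0 + dx * z2, y = -0.5 * z2,
                                        z = z2, reproj_err_px = 0,
                                        provenance = "triangulated")
  traj <- rbind(mk("digit1", -2, 0.1), mk("digit2", -0.7, 0.03),
                mk("digit3", 0.7, -0.03), mk("digit4", 2, -0.1))
  class(traj) <- c("trajectory3d", "data.frame")
  ev <- data.frame(start_frame = 0, end_frame = n - 1)
  pr <- profile_by_extent(traj, ev)
  on <- pr$mask
  expect_true(all(pr$grid[on] >= -12 & pr$grid[on] <= 3))
  expect_false(any(pr$mask[pr$grid < -12 | pr$grid > 3]))
  want <- sqrt(((2 - (-2)) + (-0.1 - 0.1) * pr$grid[on])^2)
  expect_equal(pr$aperture_mm[on], want, tolerance = 1e-9)
})

test_that("generator aperture profiles are recovered within 0.1 mm z_half", {
  pair <- default_pair()
  gt <- simulate_reach(reach_gen_params(extent_mean = 5, extent_sd = 0),
                       seed = 43)
  traj <- reconstruct_trajectory(clean_pose(gt), pair)
  ev <- detect_reaches(traj)
  pr <- profile_by_extent(traj, ev[1, ])
  ok <- pr$mask & pr$grid > -18 & pr$grid < 4
  fit <- stats::nls(a ~ 5 + 9 / (1 + exp(-s * (z - zh))),
                    data = data.frame(a = pr$aperture_mm[ok],
                                      z = pr$grid[ok]),
                    start = list(s = 1.5, zh = -6))
  expect_lt(abs(coef(fit)[["zh"]] - (-7)), 0.1)
})

test_that("sampling averages only over reaches covering the query z", {
  pair <- default_pair()
  profs <- lapply(c(3, 4, -5), function(ext) {
    gt <- simulate_reach(reach_gen_params(extent_mean = ext, extent_sd = 0),
                         seed = 50 + ext)
    traj <- reconstruct_trajectory(clean_pose(gt), pair)
    ev <- detect_reaches(traj)
    profile_by_extent(traj, ev[1, ])
  })
  s <- sample_profile(profs, 0)
  # the short (-5 mm) reach never gets to the pellet: excluded
  expect_equal(s$n, 2)
  vals <- vapply(profs[1:2], function(p) {
    p$aperture_mm[abs(p$grid) < 1e-9]
  }, 0)
  expect_equal(s$mean, mean(vals))
  s7 <- sample_profile(profs, -7)
  expect_equal(s7$n, 3)
  # brute-force mean from the interpolated arrays agrees
  i <- which(abs(extent_grid() - (-7)) < 1e-9)
  brute <- mean(vapply(profs, function(p) p$aperture_mm[i], 0))
  expect_equal(s7$mean, brute)
  expect_error(sample_profile(profs, 0.123), "grid")
})

test_that("interpolation does not overshoot on monotone segments", {
  # pchip is shape-preserving: interpolated values stay within data range
  z <- c(-15, -12, -8, -3, 1, 4)
  v <- c(5, 5.5, 8, 12, 13.5, 14)
  g <- extent_grid()
  on <- g >= -15 & g <= 4
  y <- pracma::pchip(z, v, g[on])
  expect_true(all(y >= 5 - 1e-12 & y <= 14 + 1e-12))
  expect_true(all(diff(y) > -1e-12))
})

test_that("per-reach kinematics summarize end-frame measures", {
  pair <- default_pair()
  gt <- simulate_reach(reach_gen_params(extent_mean = 4, extent_sd = 0),
                       seed = 44)
  traj <- reconstruct_trajectory(clean_pose(gt), pair)
  ev <- detect_reaches(traj)
  kin <- reach_kinematics(traj, ev)
  expect_equal(kin$max_extent_mm[1], 4, tolerance = 1e-6)
  # end aperture equals the logistic at the endpoint z
  expect_equal(kin$end_aperture_mm[1], logistic_profile(4, 5, 14, -7, 2),
               tolerance = 1e-6)
  # peak speed close to the programmed 350 mm/s (frame quantization)
  expect_lt(abs(kin$max_velocity_mm_s[1] - 350) / 350, 0.1)
})
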