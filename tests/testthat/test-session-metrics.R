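# Session metrics against brute-force oracles.

test_that("success rates follow the outcome-code arithmetic", {
  expect_equal(first_success_rate(c(1, 2, 3, 4, 7)), 0.2)
  expect_equal(any_success_rate(c(1, 2, 3, 4, 7)), 0.4)
  # non-trial codes drop out of the denominator
  expect_equal(first_success_rate(c(1, 0, 6, 5)), 1)
  expect_equal(any_success_rate(c(3, 0, 6)), 0)
  expect_true(is.na(first_success_rate(c(0, 5, 6))))
  expect_error(first_success_rate(c(1, 11)), "0..10")
  # paw-through-slot trials are excluded
  expect_equal(first_success_rate(c(1, 1, 7), c(FALSE, TRUE, FALSE)), 0.5)
})

test_that("rates match brute-force recomputation on random code lists", {
  set.seed(61)
  for (k in 1:300) {
    oc <- sample(0:10, sample(1:40, 1), replace = TRUE)
    den <- sum(oc %in% c(1, 2, 3, 4, 7))
    f <- first_success_rate(oc)
    a <- any_success_rate(oc)
    if (den == 0) {
      expect_true(is.na(f) && is.na(a))
    } else {
      expect_identical(f, sum(oc == 1) / den)
      expect_identical(a, (sum(oc == 1) + sum(oc == 2)) / den)
      expect_lte(f, a)
    }
  }
})

test_that("baseline normalization divides by the last-two-retraining mean", {
  stages <- c("retraining", "retraining", "retraining", "laser_on")
  r <- normalize_to_baseline(c(0.9, 0.5, 0.7, 0.3), stages)
  expect_equal(r$baseline, 0.6)
  expect_equal(r$normalized[4], 0.5)
  flat <- normalize_to_baseline(c(0.6, 0.6, 0.6, 0.6), stages)
  expect_equal(flat$normalized, rep(1, 4))
  expect_warning(normalize_to_baseline(c(0, 0, 0.5), stages[c(1, 2, 4)]),
                 "zero")
  expect_error(normalize_to_baseline(0.5, "retraining"), "two retraining")
})

test_that("moving blocks are trailing windows with carry-forward", {
  expect_equal(moving_block(rep(1, 15))[10:15], rep(1, 6))
  expect_true(all(is.na(moving_block(rep(1, 15))[1:9])))
  x <- moving_block(rnorm(30), carry_to = 50)
  expect_length(x, 50)
  expect_equal(x[31:50], rep(x[30], 20))
  expect_length(moving_block(numeric(0)), 0)
  # brute-force oracle on random inputs, including missing values
  set.seed(62)
  for (k in 1:100) {
    v <- rnorm(sample(10:40, 1))
    v[sample(length(v), 3)] <- NA
    got <- moving_block(v, window = 10)
    for (i in 10:length(v)) {
      expect_equal(got[i], mean(v[(i - 9):i], na.rm = TRUE))
    }
  }
})

test_that("extent stratification bins trials at 1 mm from zero", {
  tr <- data.frame(max_extent_mm = c(0.2, 0.9, 1.5, -0.3, 6.2),
                   outcome = c(1, 4, 7, 7, 1),
                   end_aperture_mm = c(10, 11, 12, 9, 13))
  st <- stratify_by_extent(tr)
  expect_equal(st$n[st$bin_lo == 0], 2)
  expect_equal(st$n[st$bin_lo == 1], 1)
  expect_equal(attr(st, "n_below_zero"), 1)
  expect_equal(st$success_rate[st$bin_lo == 0], 0.5)
  expect_true(is.na(st$success_rate[st$bin_lo == 2]))
  # brute-force oracle
  set.seed(63)
  tr <- data.frame(max_extent_mm = runif(200, -2, 9),
                   outcome = sample(c(1, 2, 4, 7), 200, replace = TRUE))
  st <- stratify_by_extent(tr)
  for (b in st$bin_lo) {
    sel <- tr$max_extent_mm >= b & tr$max_extent_mm < b + 1
    expect_equal(st$n[st$bin_lo == b], sum(sel))
    ns <- sum(tr$outcome[sel] == 1)
    nf <- sum(tr$outcome[sel] %in% c(4, 7))
    if (ns + nf > 0) {
      expect_equal(st$success_rate[st$bin_lo == b], ns / (ns + nf))
    }
  }
})

test_that("AIMs composites multiply and sum as scored", {
  s <- aims_scores(axial_amplitude = 2, axial_basic = 3,
                   limb_amplitude = 2, limb_basic = 2,
                   contralateral_rotations = 5, ipsilateral_rotations = 2)
  expect_equal(s$axial_composite, 6)
  expect_equal(s$limb_composite, 4)
  expect_equal(s$global, 10)
  expect_equal(s$rotation_bias, 3)
  z <- aims_scores(0, 3, 2, 2)
  expect_equal(z$axial_composite, 0)
  expect_equal(z$global, 4)
  expect_error(aims_scores(-1, 1, 1, 1), "non-negative")
})

test_that("session summaries aggregate the trial table", {
  des <- experiment_design(groups = "control", rats_per_group = 2,
                           trials_per_session = 30,
                           n_retraining = 1, n_laser = 1, n_occlusion = 0)
  exp1 <- generate_experiment(des, seed = 64)
  ses <- summarize_sessions(exp1$trials)
  expect_equal(nrow(ses), 4)
  r1s1 <- exp1$trials[exp1$trials$rat == ses$rat[1] &
                        exp1$trials$session == ses$session[1], ]
  expect_equal(ses$first_success[1],
               first_success_rate(r1s1$outcome, r1s1$paw_through_slot))
  expect_equal(ses$mean_extent_mm[1], mean(r1s1$max_extent_mm, na.rm = TRUE))
})
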