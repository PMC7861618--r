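# Statistical procedures: transforms, mixed models, contrasts, rank tests.

test_that("asinh transform matches its closed form", {
  expect_equal(asinh_transform(0), 0)
  expect_equal(asinh_transform(1), log(1 + sqrt(2)))
  x <- c(0.1, 1, 10, 100)
  expect_equal(asinh_transform(-x), -asinh_transform(x))
  expect_equal(asinh_transform(x), log(x + sqrt(x^2 + 1)))
})

test_that("noiseless mixed-model fits recover exact coefficients", {
  rats <- sprintf("r%02d", 1:6)
  tab <- expand.grid(rat = rats, session = 1:10)
  tab$laser <- as.integer(tab$session >= 4)
  off <- setNames(seq(-0.25, 0.25, length.out = 6), rats)
  tab$y <- 2 + 0.5 * tab$session - 1.5 * tab$laser + off[tab$rat]
  fit <- suppressWarnings(fit_lmm(tab, lmm_spec("y", ~ session + laser)))
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(co["session"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(co["laser"]), -1.5, tolerance = 1e-8)
  expect_error(fit_lmm(tab, lmm_spec("nope", ~ laser)), "missing")
})

test_that("asinh-transformed responses are fit on the transformed scale", {
  tab <- expand.grid(rat = sprintf("r%d", 1:4), session = 1:8)
  tab$y <- sinh(1 + 0.2 * tab$session)
  fit <- suppressWarnings(
    fit_lmm(tab, lmm_spec("y", ~ session, transform = "asinh")))
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(unname(co["session"]), 0.2, tolerance = 1e-6)
})

test_that("unit contrasts reproduce single-coefficient tests", {
  set.seed(71)
  tab <- expand.grid(rat = sprintf("r%d", 1:6), session = 1:12)
  tab$laser <- as.integer(tab$session >= 5)
  tab$y <- 1 + 0.3 * tab$session - tab$laser +
    rnorm(6)[as.integer(factor(tab$rat))] + rnorm(nrow(tab), 0, 0.4)
  fit <- fit_lmm(tab, lmm_spec("y", ~ session + laser))
  i <- which(fit$coefficients$term == "laser")
  ct <- contrast_test(fit, as.numeric(seq_len(3) == i))
  expect_equal(ct$statistic, fit$coefficients$stat[i], tolerance = 1e-8)
  expect_equal(ct$p, fit$coefficients$p[i], tolerance = 1e-8)
  expect_equal(ct$df, fit$coefficients$df[i], tolerance = 1e-6)
  # zero contrast: null estimate, p = 1
  z <- contrast_test(fit, rep(0, 3))
  expect_equal(z$estimate, 0)
  expect_equal(z$p, 1)
  expect_error(contrast_test(fit, c(1, 0)), "length")
})

test_that("session-difference contrasts match reference recoding", {
  set.seed(72)
  tab <- expand.grid(rat = sprintf("r%d", 1:8), sess = factor(1:4))
  tab$y <- c(0, 1.2, -0.4, 0.7)[as.integer(tab$sess)] +
    rnorm(8, 0, 0.5)[as.integer(factor(tab$rat))] + rnorm(nrow(tab), 0, 0.3)
  fit <- fit_lmm(tab, lmm_spec("y", ~ sess))
  # contrast: session 3 minus session 2 (coefficients sess3 - sess2)
  ct <- contrast_test(fit, c(0, -1, 1, 0))
  tab2 <- tab
  tab2$sess <- relevel(tab2$sess, "2")
  fit2 <- fit_lmm(tab2, lmm_spec("y", ~ sess))
  i <- which(fit2$coefficients$term == "sess3")
  expect_equal(ct$estimate, fit2$coefficients$estimate[i], tolerance = 1e-6)
  expect_equal(ct$statistic, fit2$coefficients$stat[i], tolerance = 1e-4)
})

test_that("trialwise rank-sum masks behave at the extremes", {
  a <- matrix(rnorm(60), 6, 10)
  none <- trialwise_ranksum(a, a)
  expect_false(any(none$mask))
  b <- a + 100
  all_sig <- trialwise_ranksum(a, b)
  expect_true(all(all_sig$mask))
  # fewer than 2 finite values in a group: untestable position
  b[2:6, 3] <- NA
  some <- trialwise_ranksum(a, b)
  expect_false(some$mask[3])
  expect_true(is.na(some$p[3]))
})

test_that("small-sample rank-sum p equals exhaustive enumeration", {
  a <- c(1.2, 3.4, 2.2)
  b <- c(5.1, 4.4, 6.3)
  got <- trialwise_ranksum(matrix(a), matrix(b))$p
  # enumerate all 20 assignments of ranks to group A
  pooled <- c(a, b)
  w_obs <- sum(rank(pooled)[1:3])
  combs <- combn(6, 3)
  ws <- apply(combs, 2, function(i) sum(rank(pooled)[i]))
  mu <- 3 * 7 / 2
  p_exact <- mean(abs(ws - mu) >= abs(w_obs - mu))
  expect_equal(got, p_exact)
})

test_that("kruskal-wallis, paired t, and sign tests behave canonically", {
  set.seed(73)
  x <- rnorm(12)
  kw <- kruskal_wallis(list(x, x))
  expect_equal(kw$statistic, 0, tolerance = 1e-9)
  expect_gt(kw$p, 0.99)
  # 2-group Kruskal-Wallis equals the chi-squared form of the rank sum
  a <- rnorm(8); b <- rnorm(9) + 0.8
  kw2 <- kruskal_wallis(list(a, b))
  r <- rank(c(a, b)); n <- 17
  H <- 12 / (n * (n + 1)) *
    (sum(r[1:8])^2 / 8 + sum(r[9:17])^2 / 9) - 3 * (n + 1)
  expect_equal(kw2$statistic, H, tolerance = 1e-9)
  # paired t with constant shift: t = shift / (sd/sqrt(n))
  d <- rnorm(10)
  d <- (d - mean(d)) / sd(d)        # exact zero mean, unit sd
  shift <- 3
  tt <- paired_t(d + shift, rep(0, 10))
  expect_equal(tt$statistic, shift / (1 / sqrt(10)), tolerance = 1e-9)
  expect_lt(tt$p, 0.001)
  # sign test
  st <- sign_test(c(1, 2, 3, 4, 5, 6), c(0, 1, 2, 3, 4, 5))
  expect_equal(st$statistic, 6)
  expect_equal(st$p, 2 / 64)
  tied <- sign_test(1:5, 1:5)
  expect_true(is.na(tied$p))
  expect_match(tied$method, "undefined")
})
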