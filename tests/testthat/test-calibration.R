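test_that("a noise-free line is fitted exactly", {
  x <- std_levels
  fit <- fit_calibration(x, 44446.17 * x + 5597.38)
  expect_equal(fit$slope, 44446.17)
  expect_equal(fit$intercept, 5597.38)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$residual_sd, 0)
  expect_equal(fit$n, 6L)
  expect_equal(fit$sxx, sum((x - mean(x))^2))
})

test_that("degenerate designs are rejected", {
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "3 distinct")
  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "3 distinct")
  expect_error(fit_calibration(c(1, 2, 3), c(1, 2)), "length")
})

test_that("pooled fit on generator defaults is linear and precise", {
  tabs <- generate_calibration_tables(response_model(seed = 1), curves = 5)
  long <- pool_tables(tabs)
  fit <- fit_calibration(long$concentration, long$response, curve = long$curve)
  expect_gte(fit$r_squared, 0.999)
  expect_length(fit$per_curve_slopes, 5L)
  # slope RSD is of the order of the replicate noise (anchor ~1.2 %)
  expect_lt(slope_rsd(fit), 3)
  expect_gt(slope_rsd(fit), 0.2)
})

test_that("inverse prediction matches the frozen hand-computed oracle", {
  fit <- toy_fit()
  # independent hand arithmetic: m = 2, b = +1/30, s(r) = sqrt(0.0266667)
  expect_equal(fit$slope, 2.0)
  expect_equal(fit$intercept, 1 / 30)
  est <- invert_calibration(fit, 4.0)
  expect_equal(est$x0, 1.98333333, tolerance = 1e-8)
  expect_equal(est$s_x0, 0.0942858145, tolerance = 1e-6) # 6 significant figures
})

test_that("inverse prediction is exact for noise-free data", {
  x <- std_levels
  fit <- fit_calibration(x, 44446.17 * x + 5597.38)
  for (xstar in c(0.7, 9.3, 42)) {
    est <- invert_calibration(fit, 44446.17 * xstar + 5597.38)
    expect_equal(est$x0, xstar, tolerance = 1e-12)
    expect_equal(est$s_x0, 0) # s(r) = 0 regardless of N, n
  }
  expect_error(invert_calibration(fit, numeric(0)), "non-empty")
})

test_that("the centred unknown drops the curvature term exactly", {
  fit <- toy_fit()
  est <- invert_calibration(fit, rep(fit$y_bar, 4)) # y0_bar == y_bar, N = 4
  expect_equal(est$s_x0,
               (fit$residual_sd / fit$slope) * sqrt(1 / 4 + 1 / fit$n))
})

test_that("s_x0 is non-increasing in N with the expected limit", {
  fit <- toy_fit()
  s <- vapply(1:50, function(N) invert_calibration(fit, rep(4.0, N))$s_x0,
              numeric(1))
  expect_true(all(diff(s) <= 0))
  lim <- (fit$residual_sd / fit$slope) *
    sqrt(1 / fit$n + (4.0 - fit$y_bar)^2 / (fit$slope^2 * fit$sxx))
  expect_equal(invert_calibration(fit, rep(4.0, 1e6))$s_x0, lim,
               tolerance = 1e-5)
})

test_that("relative calibration uncertainty is a guarded ratio", {
  expect_equal(relative_calibration_uncertainty(list(x0 = 9.30, s_x0 = 0.24)),
               100 * 0.24 / 9.30)
  expect_equal(relative_calibration_uncertainty(list(x0 = 9.30, s_x0 = 0)), 0)
  # scale invariance
  expect_equal(relative_calibration_uncertainty(list(x0 = 18.60, s_x0 = 0.48)),
               relative_calibration_uncertainty(list(x0 = 9.30, s_x0 = 0.24)))
  expect_error(relative_calibration_uncertainty(list(x0 = 0, s_x0 = 1)), "x0")
})

test_that("slope confidence intervals expose both constructions", {
  tabs <- generate_calibration_tables(response_model(seed = 21), curves = 5)
  long <- pool_tables(tabs)
  fit <- fit_calibration(long$concentration, long$response, curve = long$curve)
  ci_pc <- confint(fit, method = "per_curve")
  ci_cl <- confint(fit, method = "classical")
  expect_equal(dim(ci_pc), c(1L, 2L))
  expect_lt(ci_pc[1], ci_pc[2])
  expect_lt(ci_cl[1], ci_cl[2])
  # auto prefers the replicate-curve interval when curves are available
  expect_equal(confint(fit), ci_pc)
  fit1 <- fit_calibration(long$concentration, long$response)
  expect_equal(confint(fit1), confint(fit1, method = "classical"))
})

test_that("LOQ rule applies all three criteria and reports each violation", {
  expect_true(qualify_loq(96.67, 0.91, 27820, 500)$pass)
  r <- qualify_loq(94.9, 0.91, 27820, 500)
  expect_false(r$pass)
  expect_match(r$reasons, "accuracy", all = FALSE)
  # RSD of exactly 5 fails the strict "lower than 5 %" rule
  r2 <- qualify_loq(100, 5.0, 27820, 500)
  expect_false(r2$pass)
  expect_match(r2$reasons, "RSD", all = FALSE)
  r3 <- qualify_loq(100, 1, 4000, 500)
  expect_false(r3$pass)
  expect_match(r3$reasons, "blank", all = FALSE)
  # all three at once
  expect_length(qualify_loq(90, 6, 100, 500)$reasons, 3L)
})
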