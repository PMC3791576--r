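test_that("rsd is the sample-SD percent of the mean", {
  expect_equal(rsd(c(1, 2, 3)), 50)
  expect_equal(rsd(c(7, 7, 7)), 0)
  expect_error(rsd(5), ">= 2")
  expect_error(rsd(c(-1, 1)), "zero mean")
  # invariance under positive scaling
  set.seed(4)
  v <- rnorm(20, 100, 3)
  for (s in c(0.01, 3, 1e4)) expect_equal(rsd(s * v), rsd(v))
})

test_that("accuracy is percent of nominal, truncated only for display", {
  expect_equal(accuracy_pct(12, 12), 100)
  expect_equal(accuracy_pct(11.91, 12.00), 99.25)
  expect_equal(trunc_pct(accuracy_pct(14.08, 14.00)), 100.57)
  expect_equal(trunc_pct(accuracy_pct(18.30, 18.00)), 101.66) # truncation, not rounding
  expect_equal(accuracy_pct(18.30, 18.00), 101.6666, tolerance = 1e-4)
  expect_error(accuracy_pct(1, 0), "nominal")
})

test_that("recovery summaries average level recoveries and pool s(eta)", {
  exps <- list(recovery_experiment(12.00, c(11.91, 11.91, 11.91)),
               recovery_experiment(14.00, c(14.08, 14.08, 14.08)),
               recovery_experiment(18.00, c(18.30, 18.30, 18.30)))
  s <- recovery_summary(exps)
  expect_equal(trunc_pct(s$mean_recovery), 100.49)
  expect_equal(s$n, 9L)
  expect_equal(s$per_level$target, c(12, 14, 18))

  # single measurement at nominal: s(eta) absent, not zero
  one <- recovery_summary(recovery_experiment(10, 10))
  expect_equal(one$mean_recovery, 100)
  expect_true(is.na(one$s_eta))

  # symmetric over/under pairs average to exactly 100
  sym <- recovery_summary(list(recovery_experiment(10, 10 * 0.97),
                               recovery_experiment(10, 10 * 1.03)))
  expect_equal(sym$mean_recovery, 100)
  expect_error(recovery_summary(list()), "no recovery")
})

test_that("per-level s(eta) pooling is available by flag", {
  exps <- list(recovery_experiment(12, c(11.9, 12.1, 12.0)),
               recovery_experiment(18, c(18.2, 17.9, 18.0)))
  g <- recovery_summary(exps, pooling = "global")
  p <- recovery_summary(exps, pooling = "per_level")
  expect_false(isTRUE(all.equal(g$s_eta, p$s_eta)))
  expect_gt(p$s_eta, 0)
})

test_that("F factor is an area ratio with a tolerance comparator", {
  expect_equal(f_factor(100, 100), 1)
  expect_equal(f_factor(355, 100), 3.55)
  expect_error(f_factor(1, 0), "area_260")
  expect_true(f_factor_consistent(3.52, 3.55)$consistent)
  expect_false(f_factor_consistent(3.40, 3.55)$consistent)
  expect_equal(f_factor_consistent(3.40, 3.55)$difference, 0.15)
})

test_that("stress summaries recover the first-order mean", {
  # stressed == control
  s <- summarize_stress(c(100, 100, 100), 100, 0)
  expect_equal(s$recovered_pct_mean, 100)

  # simulated acidic run: k inverted from a 16.67 % target, 2 % noise
  k <- rate_from_remaining(16.67, 12)
  tab <- generate_stress_table(degradation_spec("acidic", k, 12,
                                                replicate_rsd = 2),
                               100, replicates = 500, seed = 8)
  sa <- summarize_stress(tab)
  expect_equal(sa$condition_label, "acidic")
  expect_equal(sa$recovered_pct_mean, 16.67, tolerance = 0.01)
  expect_equal(sa$impurity_count, 1L)

  # undegraded simulation: 100 %, zero impurities
  t0 <- generate_stress_table(degradation_spec("neutral-heat", 0, 12,
                                               replicate_rsd = 1),
                              100, replicates = 50, seed = 9)
  s0 <- summarize_stress(t0)
  expect_equal(s0$recovered_pct_mean, 100, tolerance = 0.01)
  expect_equal(s0$impurity_count, 0L)

  expect_error(summarize_stress(numeric(0), 100, 1), "empty")
  expect_error(summarize_stress(c(1, 2), 0, 1), "control_mean_area")
})

test_that("robustness evaluation gates each factor on every criterion", {
  nominal <- data.frame(
    factor = rep(c("flow_rate", "temperature", "pH"), each = 3),
    level = rep(c("low", "nominal", "high"), 3),
    assay_pct = 100, resolution = 9.3, plates = 11700, tailing = 1.1)
  r <- evaluate_robustness(nominal)
  expect_true(r$pass)
  expect_equal(nrow(r$per_factor), 3L)

  bad <- nominal
  bad$resolution[4] <- 8.5
  rb <- evaluate_robustness(bad)
  expect_false(rb$pass)
  failed <- rb$per_factor[!rb$per_factor$pass, ]
  expect_equal(failed$factor, "temperature") # row 4 varies temperature
  expect_false(failed$resolution_ok)
  expect_true(all(rb$per_factor$assay_ok))

  expect_error(evaluate_robustness(nominal[0, ]), "non-empty")
  expect_error(evaluate_robustness(nominal[, -3]), "missing column")
})
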