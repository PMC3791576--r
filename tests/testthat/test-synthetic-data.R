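test_that("noise-free calibration tables fall exactly on the response line", {
  tabs <- generate_calibration_tables(noiseless_model(), levels = std_levels,
                                      curves = 1)
  expect_equal(unlist(tabs[[1]], use.names = FALSE),
               44446.17 * std_levels + 5597.38)
  expect_equal(tabs[[1]][["10"]], 450059.08)
})

test_that("generator rejects bad inputs with informative messages", {
  m <- noiseless_model()
  expect_error(generate_calibration_tables(m, levels = c(0)), "0")
  expect_error(generate_calibration_tables(m, levels = c(5, -1)), "-1")
  expect_error(generate_calibration_tables(m, levels = numeric(0)), "non-empty")
  expect_error(response_model(true_slope = -1, seed = 1), "positive")
  expect_error(response_model(noise_rsd_by_level = c("5" = -0.1), seed = 1),
               ">= 0")
  expect_error(response_model(), "seed")
})

test_that("identical seed and parameters reproduce identical tables", {
  mk <- function() generate_calibration_tables(
    response_model(seed = 77), curves = 3, replicates_per_point = 2)
  expect_identical(mk(), mk())
  # a different seed changes the draw
  other <- generate_calibration_tables(response_model(seed = 78), curves = 3,
                                       replicates_per_point = 2)
  expect_false(identical(mk()[[1]], other[[1]]))
})

test_that("empirical RSD converges to the specified RSD", {
  m <- response_model(noise_rsd_by_level = c("10" = 1.5), seed = 5)
  tab <- generate_calibration_tables(m, levels = 10, curves = 1,
                                     replicates_per_point = 10000)
  expect_equal(rsd(tab[[1]][[1]]), 1.5, tolerance = 0.05)
})

test_that("nearest-level RSD lookup is used for unmapped levels", {
  m <- response_model(noise_rsd_by_level = c("0.5" = 0, "50" = 3), seed = 9)
  tab <- generate_calibration_tables(m, levels = c(1, 40), curves = 1,
                                     replicates_per_point = 200)
  expect_equal(rsd(tab[[1]][[1]] + 1e-9), 0, tolerance = 1e-6) # 1 -> map 0.5
  expect_equal(rsd(tab[[1]][[2]]), 3, tolerance = 0.5)         # 40 -> map 50
})

test_that("refitting generator output recovers the true slope within 2 %", {
  tabs <- generate_calibration_tables(response_model(seed = 11), curves = 5)
  long <- pool_tables(tabs)
  fit <- fit_calibration(long$concentration, long$response, curve = long$curve)
  expect_equal(fit$slope, 44446.17, tolerance = 0.02)
})

test_that("first-order stress kinetics hit their targets", {
  # no decay
  s0 <- degradation_spec("neutral-heat", 0, 12)
  t0 <- generate_stress_table(s0, 100, replicates = 3, seed = 1)
  expect_equal(t0$parent, rep(100, 3))

  # rate inverted from a 16.67 % remaining target
  k <- rate_from_remaining(16.67, 12)
  expect_equal(k, 0.14930, tolerance = 1e-4)
  sa <- degradation_spec("acidic", k, 12)
  ta <- generate_stress_table(sa, 100, replicates = 5, seed = 2)
  expect_equal(attr(ta, "remaining_fraction") * 100, 16.67, tolerance = 1e-12)
  expect_equal(mean(ta$parent), 16.67) # noise-free replicates

  # basic condition: two impurity channels emitted
  kb <- rate_from_remaining(10.47, 12)
  tb <- generate_stress_table(degradation_spec("basic", kb, 12,
                                               impurity_channels = 2),
                              100, replicates = 3, seed = 3)
  expect_named(tb, c("parent", "impurity_1", "impurity_2"))

  expect_error(degradation_spec("acidic", -0.1, 12), ">= 0")
  expect_error(rate_from_remaining(0, 12), "\\(0, 100\\]")
})

test_that("noise-free mass balance is exact and noisy means are unbiased", {
  k <- rate_from_remaining(10.47, 12)
  tb <- generate_stress_table(degradation_spec("basic", k, 12,
                                               impurity_channels = 2),
                              100, replicates = 4, seed = 3)
  expect_equal(tb$parent + tb$impurity_1 + tb$impurity_2, rep(100, 4))
  # uneven configurable split
  ts <- generate_stress_table(degradation_spec("basic", k, 12, 2),
                              100, replicates = 2, seed = 3,
                              impurity_split = c(0.8, 0.2))
  expect_equal(mean(ts$impurity_1) / mean(ts$impurity_2), 4)
  # multiplicative replicate noise centres on the first-order mean
  sn <- degradation_spec("acidic", k, 12, replicate_rsd = 2)
  tn <- generate_stress_table(sn, 100, replicates = 5000, seed = 4)
  expect_equal(mean(tn$parent), 10.47, tolerance = 0.01)
  expect_equal(rsd(tn$parent), 2, tolerance = 0.05)
})

test_that("synthesized Gaussian peaks integrate to their specified area", {
  ch <- synthesize_chromatogram(peak_spec(5.8, 1e5, 11511), duration = 8)
  pk <- detect_and_integrate(ch)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$area, 1e5, tolerance = 0.005)
  expect_equal(tailing_factor(pk), 1, tolerance = 0.01)
})

test_that("EMG tail constant reproduces the requested tailing factor", {
  ch <- synthesize_chromatogram(peak_spec(5.8, 4.5e5, 11511,
                                          tailing_factor = 1.1),
                                duration = 8)
  pk <- detect_and_integrate(ch)
  expect_equal(tailing_factor(pk), 1.1, tolerance = 0.05 / 1.1)
  expect_equal(pk$retention_time, 5.8, tolerance = 1e-3)
})

test_that("chromatogram synthesis validates its inputs", {
  p <- peak_spec(5.8, 1e5, 11511)
  expect_error(synthesize_chromatogram(p, duration = 4), "outside")
  expect_error(synthesize_chromatogram(p, duration = 8, sampling_interval = 0),
               "sampling_interval")
  expect_error(peak_spec(5.8, 1e5, 11511, tailing_factor = 1.2,
                         model = "gaussian"), "tailing_factor")
  expect_error(peak_spec(-1, 1e5, 11511), "retention_time")
  # noisy baseline needs a seed, and is reproducible with one
  expect_error(synthesize_chromatogram(p, 8, baseline_noise_sd = 10), "seed")
  a <- synthesize_chromatogram(p, 8, baseline_noise_sd = 10, seed = 2)
  b <- synthesize_chromatogram(p, 8, baseline_noise_sd = 10, seed = 2)
  expect_identical(a, b)
})

test_that("area tables round-trip through their delimited format", {
  tabs <- generate_calibration_tables(response_model(seed = 3), curves = 1,
                                      replicates_per_point = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_area_table(tabs[[1]], path)
  back <- read_area_table(path)
  expect_equal(names(back), names(tabs[[1]]))
  expect_equal(as.matrix(back), as.matrix(tabs[[1]]), ignore_attr = TRUE)
  bad <- tabs[[1]]; bad[1, 2] <- NA
  expect_error(write_area_table(bad, path), "missing")
})
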