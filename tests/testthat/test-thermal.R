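test_that("a noise-free endotherm is located within one sampling interval", {
  for (td in c(62.57, 66.8)) {
    tg <- generate_thermogram(thermogram_params(td_C = td, noise_sd_mW = 0))
    res <- detect_denaturation(tg)
    expect_lt(abs(res$td_C - td), 0.1)
    expect_gt(res$peak_height_mW, 1.5)
  }
})

test_that("a peakless trace raises a no-peak error", {
  tg <- generate_thermogram(thermogram_params(peak_depth_mW = 0,
                                              baseline_intercept_mW = 3,
                                              baseline_slope_mW_per_C = 0.05,
                                              noise_sd_mW = 0))
  expect_error(detect_denaturation(tg), "no detectable")
  tg2 <- generate_thermogram(thermogram_params(peak_depth_mW = 0,
                                               noise_sd_mW = 0.05, seed = 2))
  expect_error(detect_denaturation(tg2), "no detectable")
})

test_that("the detected Td is invariant to the baseline slope", {
  base <- NULL
  for (slope in c(-0.1, 0, 0.04, 0.2)) {
    tg <- generate_thermogram(thermogram_params(
      td_C = 64.2, baseline_intercept_mW = 2,
      baseline_slope_mW_per_C = slope, noise_sd_mW = 0))
    td <- detect_denaturation(tg)$td_C
    if (is.null(base)) base <- td
    expect_lt(abs(td - base), 1e-6)
  }
})

test_that("the generated trace minus the analytic baseline is the negative Gaussian", {
  p <- thermogram_params(td_C = 66.8, peak_width_C = 2.5, peak_depth_mW = 2,
                         baseline_intercept_mW = 1.5,
                         baseline_slope_mW_per_C = 0.03, noise_sd_mW = 0)
  tg <- generate_thermogram(p)
  gauss <- -2 * exp(-(tg$temperature_C - 66.8)^2 / (2 * 2.5^2))
  expect_equal(tg$heat_flow_mW - (1.5 + 0.03 * tg$temperature_C), gauss,
               tolerance = 1e-12)
})

test_that("baseline subtraction zeroes the baseline-window means", {
  tg <- generate_thermogram(thermogram_params(
    baseline_intercept_mW = 4, baseline_slope_mW_per_C = 0.05,
    noise_sd_mW = 0.05, seed = 8))
  res <- detect_denaturation(tg)
  b <- res$baseline
  fit <- b["intercept"] + b["slope"] * tg$temperature_C
  pre <- tg$temperature_C >= res$pre_window_C[1] &
    tg$temperature_C <= res$pre_window_C[2]
  resid <- tg$heat_flow_mW - fit
  expect_lt(abs(mean(resid[pre])), 3 * 0.05 / sqrt(sum(pre)))
})

test_that("baseline windows overlapping the peak are flagged", {
  tg <- generate_thermogram(thermogram_params(td_C = 20, peak_width_C = 4,
                                              noise_sd_mW = 0))
  res <- detect_denaturation(tg, pre_window_C = c(10, 18),
                             post_window_C = c(85, 95))
  expect_true(length(res$warnings) > 0)
})

test_that("endotherm-up traces are handled by the sign switch", {
  p <- thermogram_params(td_C = 65, noise_sd_mW = 0)
  tg <- generate_thermogram(p)
  flipped <- thermogram(tg$temperature_C, -tg$heat_flow_mW)
  expect_lt(abs(detect_denaturation(flipped, sign = "endo_up")$td_C - 65),
            0.1)
})

test_that("thermogram parameter invariants are enforced", {
  expect_error(thermogram_params(td_C = 5), "outside the scan range")
  expect_error(thermogram_params(peak_width_C = 0), "positive")
  expect_error(thermogram(c(1, 2, 2, 3, 4), rep(0, 5)), "increasing")
})
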