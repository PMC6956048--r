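test_that("zero target density yields an empty field on a uniform background", {
  p <- fibril_field_params(target_density = 0, field_width_px = 64,
                           field_height_px = 64, noise_sd = 0,
                           blur_sigma_px = 0, seed = 1)
  f <- generate_fibril_field(p)
  expect_identical(nrow(f$centers_nm), 0L)
  expect_identical(length(f$diameters_nm), 0L)
  expect_equal(f$realized_density, 0)
  expect_true(all(f$image == p$background_intensity))
})

test_that("realized density tracks the target and is recomputable from the truth record", {
  p <- fibril_field_params(target_density = 50, field_width_px = 2048,
                           field_height_px = 2048, pixel_size_nm = 2,
                           noise_sd = 0, blur_sigma_px = 0, seed = 101)
  f <- generate_fibril_field(p)
  area_um2 <- (2048 * 2 / 1000)^2
  expect_identical(length(f$diameters_nm), nrow(f$centers_nm))
  expect_equal(f$realized_density, nrow(f$centers_nm) / area_um2)
  expect_lt(abs(f$realized_density - 50) / 50, 0.05)
})

test_that("every generated field satisfies the hard-core separation (brute force)", {
  for (seed in c(3, 4)) {
    p <- fibril_field_params(target_density = 80, diameter_mean_nm = 28,
                             min_gap_nm = 6, field_width_px = 600,
                             field_height_px = 600, noise_sd = 0,
                             blur_sigma_px = 0, seed = seed)
    f <- generate_fibril_field(p)
    n <- nrow(f$centers_nm)
    expect_gt(n, 10)
    ok <- TRUE
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      gap <- sqrt(sum((f$centers_nm[i, ] - f$centers_nm[j, ])^2)) -
        (f$diameters_nm[i] + f$diameters_nm[j]) / 2
      if (gap < 6 - 1e-9) ok <- FALSE
    }
    expect_true(ok)
  }
})

test_that("empirical diameter moments match the parameters within 3 standard errors", {
  for (law in c("lognormal", "truncated-normal")) {
    p <- fibril_field_params(target_density = 60, diameter_mean_nm = 30,
                             diameter_sd_nm = 5, diameter_law = law,
                             field_width_px = 1600, field_height_px = 1600,
                             noise_sd = 0, blur_sigma_px = 0, seed = 9)
    f <- generate_fibril_field(p)
    n <- length(f$diameters_nm)
    expect_gte(n, 500)
    # RSA thins large disks slightly more; 3 SE of the mean still holds at
    # these packing fractions
    expect_lt(abs(mean(f$diameters_nm) - 30), 3 * 5 / sqrt(n))
    se_sd <- 5 / sqrt(2 * (n - 1))
    expect_lt(abs(sd(f$diameters_nm) - 5), 3 * se_sd * 3)
  }
})

test_that("generation is bit-reproducible for a fixed seed", {
  p <- fibril_field_params(target_density = 40, field_width_px = 256,
                           field_height_px = 256, seed = 77)
  f1 <- generate_fibril_field(p)
  f2 <- generate_fibril_field(p)
  expect_identical(f1$centers_nm, f2$centers_nm)
  expect_identical(f1$diameters_nm, f2$diameters_nm)
  expect_identical(f1$image, f2$image)
  p2 <- fibril_field_params(target_density = 40, field_width_px = 256,
                            field_height_px = 256, seed = 78)
  expect_false(identical(generate_fibril_field(p2)$centers_nm,
                         f1$centers_nm))
})

test_that("infeasible packings and inverted contrast are rejected up front", {
  expect_error(fibril_field_params(target_density = 500,
                                   diameter_mean_nm = 40, min_gap_nm = 10),
               "0.55")
  expect_error(fibril_field_params(fibril_intensity = 0.8,
                                   background_intensity = 0.5),
               "dark")
  expect_error(fibril_field_params(diameter_mean_nm = -1), "positive")
})
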