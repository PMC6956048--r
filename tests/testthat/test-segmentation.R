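test_that("a contrast-free image binarizes to all background", {
  img <- matrix(0.5, 32, 32)
  mask <- binarize_adaptive(img, segmentation_config(offset = 0.05))
  expect_false(any(mask))
})

test_that("adaptive threshold equals the brute-force local-mean comparison", {
  # 7x7 with a single dark pixel, window 3
  img <- matrix(0.8, 7, 7)
  img[4, 3] <- 0.1
  cfg <- segmentation_config(local_window_px = 3, offset = 0.05)
  oracle <- img < brute_local_mean(img, 3) - 0.05
  expect_identical(unname(binarize_adaptive(img, cfg)), oracle)
  # random image, larger window, both polarities
  set.seed(5)
  img2 <- matrix(runif(9 * 11), 9, 11)
  for (k in c(3, 5)) {
    cfg2 <- segmentation_config(local_window_px = k, offset = 0.02)
    expect_identical(unname(binarize_adaptive(img2, cfg2)),
                     img2 < brute_local_mean(img2, k) - 0.02)
    cfg3 <- segmentation_config(local_window_px = k, offset = 0.02,
                                polarity = "bright_foreground")
    expect_identical(unname(binarize_adaptive(img2, cfg3)),
                     img2 > brute_local_mean(img2, k) + 0.02)
  }
})

test_that("foreground area of a noise-free field matches the analytic disk area", {
  p <- fibril_field_params(target_density = 40, field_width_px = 800,
                           field_height_px = 800, pixel_size_nm = 2,
                           noise_sd = 0, seed = 21)
  f <- generate_fibril_field(p)
  mask <- binarize_adaptive(f$image)
  analytic_px <- sum(pi * (f$diameters_nm / 2 / 2)^2)
  expect_lt(abs(sum(mask) - analytic_px) / analytic_px, 0.05)
})

test_that("an empty mask yields an empty detection table", {
  det <- detect_fibrils(matrix(FALSE, 20, 20), pixel_size_nm = 2)
  expect_s3_class(det, "fibril_detections")
  expect_identical(nrow(det), 0L)
})

test_that("an ideal disk is measured at its analytic equivalent diameter", {
  mask <- make_disk_mask(64, 64, 32, 32, radius = 10)
  det <- detect_fibrils(mask, pixel_size_nm = 2)
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$equivalent_diameter_nm - 40), 2)
  expect_lt(abs(det$circularity - 1), 0.1)
  expect_lt(abs(det$centroid_row - 31.5), 0.1)
})

test_that("corner-touching disks merge under 8- but not 4-connectivity", {
  mask <- matrix(FALSE, 20, 20)
  mask[3:8, 3:8] <- TRUE
  mask[9:14, 9:14] <- TRUE
  expect_true(mask[8, 8] && mask[9, 9] && !mask[8, 9] && !mask[9, 8])
  loose <- function(conn)
    detect_fibrils(mask, 2, segmentation_config(min_area_px = 1,
                                                min_circularity = 0,
                                                connectivity = conn))
  expect_identical(nrow(loose(8)), 1L)
  expect_identical(nrow(loose(4)), 2L)
})

test_that("increasing the offset never increases the foreground count", {
  set.seed(11)
  img <- matrix(runif(80 * 80), 80, 80)
  counts <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(off)
    sum(binarize_adaptive(img, segmentation_config(offset = off))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("invalid segmentation inputs are rejected", {
  expect_error(segmentation_config(local_window_px = 4), "odd")
  expect_error(segmentation_config(min_circularity = 1.2), "\\[0, 1\\]")
  expect_error(segmentation_config(connectivity = 6), "4 or 8")
  expect_error(binarize_adaptive(array(0.5, c(8, 8, 3))), "matrix")
})
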