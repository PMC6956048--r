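test_that("no detections means zero density, with the full window count", {
  det <- fake_detections(numeric(0), numeric(0), c(512L, 512L))
  est <- estimate_density(det, config = density_config(128, 50, seed = 1))
  expect_equal(est$density_per_um2, 0)
  expect_equal(est$median_count, 0)
  expect_length(est$per_window_counts, 50)
})

test_that("per-window counts match the brute-force double loop", {
  # regular grid of centroids whose spacing divides the window size
  g <- as.matrix(expand.grid(seq(10, 490, by = 20), seq(10, 490, by = 20)))
  det <- fake_detections(g[, 1], g[, 2], c(512L, 512L))
  cfg <- density_config(window_px = 100, n_windows = 80, seed = 42)
  est <- estimate_density(det, config = cfg)
  corners <- withr::with_seed(42L, list(
    r0 = sample.int(512 - 100 + 1, 80, replace = TRUE) - 1L,
    c0 = sample.int(512 - 100 + 1, 80, replace = TRUE) - 1L))
  oracle <- brute_window_counts(g[, 1], g[, 2], corners$r0, corners$c0, 100)
  expect_identical(est$per_window_counts, oracle)
  # irregular random fields too
  for (seed in 1:3) {
    set.seed(seed + 100)
    det2 <- fake_detections(runif(200, 0, 511), runif(200, 0, 511),
                            c(512L, 512L))
    cfg2 <- density_config(150, 60, seed = seed)
    est2 <- estimate_density(det2, config = cfg2)
    corners2 <- withr::with_seed(as.integer(seed), list(
      r0 = sample.int(512 - 150 + 1, 60, replace = TRUE) - 1L,
      c0 = sample.int(512 - 150 + 1, 60, replace = TRUE) - 1L))
    expect_identical(est2$per_window_counts,
                     brute_window_counts(det2$centroid_row,
                                         det2$centroid_col,
                                         corners2$r0, corners2$c0, 150))
  }
})

test_that("the default protocol samples exactly 200 windows of 300 px", {
  det <- fake_detections(runif(50, 0, 400), runif(50, 0, 400),
                         c(512L, 512L))
  est <- estimate_density(det, config = density_config(seed = 7))
  expect_length(est$per_window_counts, 200)
  expect_identical(est$window_px, 300L)
  expect_equal(est$window_area_um2, (300 * 2 / 1000)^2)
})

test_that("density estimates are deterministic under a fixed seed", {
  set.seed(9)
  det <- fake_detections(runif(300, 0, 1000), runif(300, 0, 1000),
                         c(1024L, 1024L))
  e1 <- estimate_density(det, config = density_config(300, 200, seed = 5))
  e2 <- estimate_density(det, config = density_config(300, 200, seed = 5))
  expect_identical(e1$per_window_counts, e2$per_window_counts)
  expect_identical(e1$density_per_um2, e2$density_per_um2)
})

test_that("windows larger than the image are rejected", {
  det <- fake_detections(1, 1, c(200L, 200L))
  expect_error(estimate_density(det, config = density_config(300, 10)),
               "does not fit")
})

test_that("aggregation pools counts into a single median", {
  mk <- function(counts) stromaquant:::new_density_estimate(
    counts, window_px = 300, pixel_size_nm = 2, n_images = 1L, seed = NULL)
  # median of the nine pooled integers {0,0,1,2,2,3,1,1,2} is 1
  agg <- aggregate_density(list(mk(c(0, 0, 1)), mk(c(2, 2, 3)),
                                mk(c(1, 1, 2))))
  expect_equal(agg$median_count, 1)
  expect_equal(agg$density_per_um2, 1 / (300 * 2 / 1000)^2)
  expect_identical(agg$n_images, 3L)
  expect_length(agg$per_window_counts, 9)
  # idempotence on identical inputs
  same <- mk(c(4, 5, 6, 7))
  agg2 <- aggregate_density(list(same, same, same))
  expect_equal(agg2$density_per_um2, same$density_per_um2)
})

test_that("aggregation refuses fewer than the minimum number of images", {
  mk <- function() stromaquant:::new_density_estimate(
    c(1, 2), 300, 2, 1L, NULL)
  expect_error(aggregate_density(list(mk(), mk()), min_images = 3),
               "at least 3 images, got 2")
  expect_error(aggregate_density(list(mk(), mk(),
                                      stromaquant:::new_density_estimate(
                                        c(1, 2), 200, 2, 1L, NULL))),
               "window geometry")
})
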