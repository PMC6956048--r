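# Independent brute-force oracles kept deliberately naive: double loops and
# direct definitions, sharing no code with the implementation.

# Local mean with symmetric (edge-duplicating) reflection, per-pixel loops.
brute_local_mean <- function(img, k) {
  p <- (k - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  reflect <- function(i, n) {
    if (i < 1) 1 - i else if (i > n) 2 * n - i + 1 else i
  }
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (dr in -p:p) for (dc in -p:p)
      acc <- acc + img[reflect(r + dr, nr), reflect(c + dc, nc)]
    out[r, c] <- acc / k^2
  }
  out
}

# Per-window centroid counts by explicit double loop.
brute_window_counts <- function(rows, cols, r0, c0, w) {
  out <- integer(length(r0))
  for (i in seq_along(r0)) {
    n <- 0L
    for (j in seq_along(rows)) {
      if (rows[j] >= r0[i] && rows[j] < r0[i] + w &&
          cols[j] >= c0[i] && cols[j] < c0[i] + w) n <- n + 1L
    }
    out[i] <- n
  }
  out
}

# Ideal rasterized disk: pixel centers within radius of the disk center
# (0-based indices, pixel (r, c) centered at (r + 0.5, c + 0.5)).
make_disk_mask <- function(nr, nc, ctr_row, ctr_col, radius) {
  rr <- matrix(seq_len(nr) - 0.5, nr, nc)
  cc <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  (rr - ctr_row)^2 + (cc - ctr_col)^2 <= radius^2
}

# Detection-like data frame from bare centroids, for estimator tests.
fake_detections <- function(rows, cols, shape, pixel_size_nm = 2) {
  d <- data.frame(centroid_row = rows, centroid_col = cols,
                  area_px = rep(50, length(rows)),
                  perimeter_px = rep(25, length(rows)),
                  equivalent_diameter_nm = rep(16, length(rows)),
                  circularity = rep(1, length(rows)))
  attr(d, "pixel_size_nm") <- pixel_size_nm
  attr(d, "image_shape_px") <- shape
  class(d) <- c("fibril_detections", "data.frame")
  d
}

# Index of the nearest ground-truth fibril for each detection. Truth centers
# (nm) are converted to the 0-based pixel-index convention of centroids.
match_truth <- function(det, field) {
  ps <- field$params$pixel_size_nm
  tr <- field$centers_nm[, "y_nm"] / ps - 0.5
  tc <- field$centers_nm[, "x_nm"] / ps - 0.5
  vapply(seq_len(nrow(det)), function(i)
    which.min((tr - det$centroid_row[i])^2 + (tc - det$centroid_col[i])^2),
    integer(1))
}

# Margin (px) between each matched truth disk and the image border; disks
# with negative margin are clipped by the field of view.
truth_edge_margin <- function(det, field, idx) {
  ps <- field$params$pixel_size_nm
  tr <- field$centers_nm[idx, "y_nm"] / ps - 0.5
  tc <- field$centers_nm[idx, "x_nm"] / ps - 0.5
  rad <- field$diameters_nm[idx] / 2 / ps
  h <- field$params$field_height_px; w <- field$params$field_width_px
  pmin(tr - rad, tc - rad, (h - 1) - (tr + rad), (w - 1) - (tc + rad))
}
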