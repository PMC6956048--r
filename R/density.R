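#' Configuration for randomized-window density estimation
#'
#' The estimator drops square counting windows uniformly at random (with
#' replacement) inside the image and records the number of fibril centroids
#' falling in each; the density is the median count divided by the window
#' area. Defaults follow the protocol of the underlying study: 200 windows
#' of 300 x 300 pixels per image, at least 3 images per specimen.
#'
#' @param window_px Window side length in pixels (default 300).
#' @param n_windows Number of random windows per image (default 200).
#' @param min_images Minimum number of images required by
#'   [aggregate_density()] (default 3).
#' @param seed Integer seed for the window draws, or `NULL`.
#' @return An object of class `density_config`.
#' @export
density_config <- function(window_px = 300L, n_windows = 200L,
                           min_images = 3L, seed = NULL) {
  window_px <- as.integer(window_px)
  n_windows <- as.integer(n_windows)
  if (window_px < 1L) stop("`window_px` must be >= 1", call. = FALSE)
  if (n_windows < 1L) stop("`n_windows` must be >= 1", call. = FALSE)
  if (min_images < 1L) stop("`min_images` must be >= 1", call. = FALSE)
  structure(list(window_px = window_px, n_windows = n_windows,
                 min_images = as.integer(min_images), seed = seed),
            class = "density_config")
}

#' Estimate fibril density by randomized counting windows
#'
#' Draws `n_windows` top-left corners uniformly (with replacement) on the
#' integer grid `[0, H - w] x [0, W - w]`, so every window lies fully inside
#' the image. A fibril belongs to a window when its centroid lies in the
#' half-open square `[r0, r0 + w) x [c0, c0 + w)`; half-open bounds mean
#' abutting windows can never double-count a centroid. The density is the
#' median per-window count divided by the window area in square micrometres.
#'
#' @param detections A `fibril_detections` data frame (or anything with
#'   `centroid_row` / `centroid_col` columns in 0-based pixel units).
#' @param image_shape_px Integer vector `c(height, width)`; defaults to the
#'   `image_shape_px` attribute of `detections`.
#' @param pixel_size_nm Physical pixel size; defaults to the detections
#'   attribute.
#' @param config A [density_config()].
#' @return An object of class `density_estimate`: list with
#'   `per_window_counts`, `window_px`, `window_area_um2`, `median_count`,
#'   `density_per_um2` (= `median_count / window_area_um2`), `n_images`,
#'   `seed`.
#' @export
estimate_density <- function(detections, image_shape_px = NULL,
                             pixel_size_nm = NULL,
                             config = density_config()) {
  stopifnot(inherits(config, "density_config"))
  if (is.null(image_shape_px))
    image_shape_px <- attr(detections, "image_shape_px")
  if (is.null(pixel_size_nm))
    pixel_size_nm <- attr(detections, "pixel_size_nm")
  if (is.null(image_shape_px) || is.null(pixel_size_nm))
    stop("`image_shape_px` and `pixel_size_nm` must be supplied when not ",
         "carried by `detections`", call. = FALSE)
  h <- image_shape_px[1]; w <- image_shape_px[2]; k <- config$window_px
  if (k > h || k > w)
    stop(sprintf("window of %d px does not fit inside a %d x %d image",
                 k, h, w), call. = FALSE)
  counts <- with_seed_(config$seed, {
    r0 <- sample.int(h - k + 1L, config$n_windows, replace = TRUE) - 1L
    c0 <- sample.int(w - k + 1L, config$n_windows, replace = TRUE) - 1L
    window_counts(as.numeric(detections$centroid_row),
                  as.numeric(detections$centroid_col), r0, c0, k)
  })
  new_density_estimate(counts, k, pixel_size_nm, n_images = 1L,
                       seed = config$seed)
}

new_density_estimate <- function(counts, window_px, pixel_size_nm,
                                 n_images, seed) {
  area_um2 <- (window_px * pixel_size_nm / 1000)^2
  med <- median(as.numeric(counts))
  structure(list(per_window_counts = as.integer(counts),
                 window_px = as.integer(window_px),
                 pixel_size_nm = pixel_size_nm,
                 window_area_um2 = area_um2, median_count = med,
                 density_per_um2 = med / area_um2,
                 n_images = as.integer(n_images), seed = seed),
            class = "density_estimate")
}

#' Aggregate per-image density estimates
#'
#' Pools the per-window counts of several images of the same specimen and
#' takes a single median over the pooled counts, enforcing a minimum number
#' of images. All estimates must share the same window geometry.
#'
#' @param per_image List of [estimate_density()] results.
#' @param min_images Minimum number of images (default 3).
#' @return A pooled `density_estimate` with `n_images` set to the total.
#' @export
aggregate_density <- function(per_image, min_images = 3L) {
  if (length(per_image) < min_images)
    stop(sprintf("aggregation needs at least %d images, got %d",
                 min_images, length(per_image)), call. = FALSE)
  stopifnot(all(vapply(per_image, inherits, TRUE, "density_estimate")))
  wpx <- vapply(per_image, `[[`, 1L, "window_px")
  ps <- vapply(per_image, `[[`, 1, "pixel_size_nm")
  if (length(unique(wpx)) != 1L || length(unique(ps)) != 1L)
    stop("all estimates must share the same window geometry", call. = FALSE)
  counts <- unlist(lapply(per_image, `[[`, "per_window_counts"))
  new_density_estimate(counts, wpx[1], ps[1],
                       n_images = sum(vapply(per_image, `[[`, 1L, "n_images")),
                       seed = per_image[[1]]$seed)
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf(
    "<density_estimate> %.2f fibrils/um^2 (median count %.1f in %.3f um^2 windows, %d windows, %d image%s)\n",
    x$density_per_um2, x$median_count, x$window_area_um2,
    length(x$per_window_counts), x$n_images, if (x$n_images > 1) "s" else ""))
  invisible(x)
}

#' Summarize a fibril diameter distribution
#'
#' Computes location/spread summaries and a histogram of equivalent
#' diameters. Quartiles use linear interpolation (R's default type-7 rule);
#' histogram bins start at 0 nm with the given width.
#'
#' @param detections A `fibril_detections` data frame, or a numeric vector
#'   of diameters in nm.
#' @param bin_width_nm Histogram bin width, nm (default 2).
#' @return An object of class `diameter_distribution`: list with
#'   `diameters_nm`, `n`, `median_nm`, `iqr_nm`, `mean_nm`, `sd_nm`,
#'   `histogram` (list of `breaks_nm`, `counts`). Summaries are `NA` for
#'   empty input.
#' @export
diameter_distribution <- function(detections, bin_width_nm = 2) {
  stop_if_not_scalar_pos(bin_width_nm, "bin_width_nm")
  d <- if (is.numeric(detections)) detections
       else detections$equivalent_diameter_nm
  n <- length(d)
  if (n == 0L) {
    return(structure(list(diameters_nm = numeric(0), n = 0L,
                          median_nm = NA_real_, iqr_nm = NA_real_,
                          mean_nm = NA_real_, sd_nm = NA_real_,
                          histogram = list(breaks_nm = numeric(0),
                                           counts = integer(0))),
                     class = "diameter_distribution"))
  }
  q <- unname(quantile(d, c(0.25, 0.5, 0.75), type = 7))
  breaks <- seq(0, bin_width_nm * ceiling(max(d) / bin_width_nm),
                by = bin_width_nm)
  if (length(breaks) < 2) breaks <- c(0, bin_width_nm)
  counts <- tabulate(findInterval(d, breaks, left.open = TRUE,
                                  rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  structure(list(diameters_nm = d, n = n, median_nm = q[2],
                 iqr_nm = q[3] - q[1], mean_nm = mean(d),
                 sd_nm = if (n > 1) sd(d) else 0,
                 histogram = list(breaks_nm = breaks, counts = counts)),
            class = "diameter_distribution")
}

#' @export
print.diameter_distribution <- function(x, ...) {
  cat(sprintf(
    "<diameter_distribution> n = %d, median %.1f nm (IQR %.1f), mean %.1f nm (SD %.1f)\n",
    x$n, x$median_nm, x$iqr_nm, x$mean_nm, x$sd_nm))
  invisible(x)
}
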