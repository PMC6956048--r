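#' Segmentation configuration for fibril detection
#'
#' Controls the adaptive binarization and the connected-component filters.
#' Binarization compares each pixel with the mean gray level of its local
#' square neighborhood (mean-C adaptive thresholding); detection labels the
#' resulting mask and discards components by area and circularity.
#'
#' @param local_window_px Odd side length (>= 3) of the local-mean
#'   neighborhood, pixels.
#' @param offset Gray-level offset subtracted from (dark foreground) or
#'   added to (bright foreground) the local mean before comparison.
#' @param polarity `"dark_foreground"` (TEM fibrils, the default) or
#'   `"bright_foreground"`.
#' @param method `"mean"` (arithmetic local mean, default) or `"gaussian"`
#'   (Gaussian-weighted mean with sigma `local_window_px / 6`).
#' @param min_area_px,max_area_px Component area bounds in pixels squared.
#' @param min_circularity Minimum circularity `4 pi A / P^2` in \[0, 1\];
#'   merged fibril blobs score low and are discarded.
#' @param connectivity Pixel connectivity for component labeling, 4 or 8.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(local_window_px = 51L, offset = 0.2,
                                polarity = c("dark_foreground",
                                             "bright_foreground"),
                                method = c("mean", "gaussian"),
                                min_area_px = 20, max_area_px = 1e4,
                                min_circularity = 0.6,
                                connectivity = 8L) {
  polarity <- match.arg(polarity)
  method <- match.arg(method)
  local_window_px <- as.integer(local_window_px)
  if (local_window_px < 3L || local_window_px %% 2L == 0L)
    stop("`local_window_px` must be an odd integer >= 3", call. = FALSE)
  if (min_circularity < 0 || min_circularity > 1)
    stop("`min_circularity` must be in [0, 1]", call. = FALSE)
  if (min_area_px >= max_area_px)
    stop("`min_area_px` must be below `max_area_px`", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  structure(list(local_window_px = local_window_px, offset = offset,
                 polarity = polarity, method = method,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 min_circularity = min_circularity,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_config")
}

# Local mean over a k x k neighborhood with edge-reflected (symmetric)
# padding, computed with an integral image: O(N) regardless of k.
local_mean <- function(img, k) {
  p <- (k - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  if (k > 2 * nr || k > 2 * nc)
    stop("`local_window_px` too large for this image", call. = FALSE)
  ridx <- c(p:1, 1:nr, nr:(nr - p + 1L))[seq_len(nr + 2L * p)]
  cidx <- c(p:1, 1:nc, nc:(nc - p + 1L))[seq_len(nc + 2L * p)]
  pad <- img[ridx, cidx, drop = FALSE]
  S <- rbind(0, apply(pad, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  i0 <- seq_len(nr); j0 <- seq_len(nc)
  (S[i0 + k, j0 + k, drop = FALSE] - S[i0, j0 + k, drop = FALSE] -
     S[i0 + k, j0, drop = FALSE] + S[i0, j0, drop = FALSE]) / (k * k)
}

#' Adaptive (local-mean) binarization
#'
#' A pixel is foreground when its intensity deviates from the mean of its
#' `local_window_px` x `local_window_px` neighborhood by more than `offset`
#' in the foreground direction: below `mean - offset` for dark foreground,
#' above `mean + offset` for bright foreground. Neighborhoods are padded by
#' edge reflection.
#'
#' @param image Single-channel numeric matrix with values in \[0, 1\].
#' @param config A [segmentation_config()].
#' @return A logical matrix of the same shape (`TRUE` = foreground).
#' @export
binarize_adaptive <- function(image, config = segmentation_config()) {
  stopifnot(inherits(config, "segmentation_config"))
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a single-channel numeric matrix", call. = FALSE)
  mu <- if (config$method == "mean") {
    local_mean(image, config$local_window_px)
  } else {
    EBImage::gblur(image, sigma = config$local_window_px / 6)
  }
  if (config$polarity == "dark_foreground") image < mu - config$offset
  else image > mu + config$offset
}

#' Detect fibril cross-sections in a binary mask
#'
#' Labels connected components at the configured connectivity, then filters
#' by pixel area and circularity. Per component it reports the sub-pixel
#' centroid (mean of 0-based pixel indices, row/col), area, perimeter,
#' equivalent-circle diameter `2 sqrt(A / pi) * pixel_size_nm`, and
#' circularity `4 pi A / P^2`. The perimeter is the count of exposed
#' 4-neighbor pixel edges scaled by `pi / 4`, which is unbiased for convex
#' digital disks, so ideal fibril sections score circularity ~1.
#'
#' @param mask Logical matrix from [binarize_adaptive()].
#' @param pixel_size_nm Physical pixel size, nm per pixel.
#' @param config A [segmentation_config()].
#' @return A data frame of class `fibril_detections`, one row per retained
#'   component, sorted by centroid (row, then col): columns `centroid_row`,
#'   `centroid_col`, `area_px`, `perimeter_px`, `equivalent_diameter_nm`,
#'   `circularity`. The pixel size is attached as attribute
#'   `pixel_size_nm`, the mask shape as `image_shape_px`.
#' @export
detect_fibrils <- function(mask, pixel_size_nm,
                           config = segmentation_config()) {
  stopifnot(inherits(config, "segmentation_config"), is.matrix(mask))
  stop_if_not_scalar_pos(pixel_size_nm, "pixel_size_nm")
  storage.mode(mask) <- "logical"
  if (!any(mask)) return(empty_detections(pixel_size_nm, dim(mask)))
  lab <- label_components(mask, config$connectivity)
  feats <- component_features(lab)
  if (nrow(feats) == 0L) return(empty_detections(pixel_size_nm, dim(mask)))
  perimeter <- feats$boundary_edges * pi / 4
  circ <- 4 * pi * feats$area_px / perimeter^2
  keep <- feats$area_px >= config$min_area_px &
    feats$area_px <= config$max_area_px &
    circ >= config$min_circularity
  feats <- feats[keep, , drop = FALSE]
  out <- data.frame(
    centroid_row = feats$centroid_row,
    centroid_col = feats$centroid_col,
    area_px = feats$area_px,
    perimeter_px = perimeter[keep],
    equivalent_diameter_nm = 2 * sqrt(feats$area_px / pi) * pixel_size_nm,
    circularity = circ[keep])
  out <- out[order(out$centroid_row, out$centroid_col), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pixel_size_nm") <- pixel_size_nm
  attr(out, "image_shape_px") <- dim(mask)
  class(out) <- c("fibril_detections", "data.frame")
  out
}

empty_detections <- function(pixel_size_nm, shape) {
  out <- data.frame(centroid_row = numeric(0), centroid_col = numeric(0),
                    area_px = numeric(0), perimeter_px = numeric(0),
                    equivalent_diameter_nm = numeric(0),
                    circularity = numeric(0))
  attr(out, "pixel_size_nm") <- pixel_size_nm
  attr(out, "image_shape_px") <- shape
  class(out) <- c("fibril_detections", "data.frame")
  out
}

#' Segment an image end to end
#'
#' Convenience wrapper: [binarize_adaptive()] then [detect_fibrils()].
#'
#' @inheritParams binarize_adaptive
#' @inheritParams detect_fibrils
#' @param image Single-channel numeric matrix in \[0, 1\].
#' @return A `fibril_detections` data frame.
#' @export
segment_fibrils <- function(image, pixel_size_nm,
                            config = segmentation_config()) {
  detect_fibrils(binarize_adaptive(image, config), pixel_size_nm, config)
}
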