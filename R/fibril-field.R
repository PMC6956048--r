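#' Parameters for a synthetic collagen fibril field
#'
#' Describes a hard-core point process of near-circular fibril cross-sections
#' together with the raster rendering that turns it into a TEM-like image:
#' dark disks on a brighter background, Gaussian optics blur, then additive
#' detector noise. All lengths are physical (nm); the raster geometry is set
#' by `field_width_px`, `field_height_px` and `pixel_size_nm`.
#'
#' The requested density must be achievable by sequential hard-core packing:
#' `target_density * pi/4 * (diameter_mean_nm + min_gap_nm)^2 * 1e-6` must be
#' below 0.55, the practical jamming fraction of random sequential adsorption
#' of disks. Denser requests are rejected up front.
#'
#' @param target_density Fibrils per square micrometre (>= 0).
#' @param diameter_mean_nm,diameter_sd_nm Mean and SD of the fibril diameter
#'   law, in nm.
#' @param diameter_law `"lognormal"` (right-skewed, the default) or
#'   `"truncated-normal"` (symmetric, truncated at zero).
#' @param min_gap_nm Minimum edge-to-edge separation between fibrils (>= 0).
#' @param field_width_px,field_height_px Raster size in pixels.
#' @param pixel_size_nm Physical pixel size, nm per pixel.
#' @param fibril_intensity,background_intensity Gray levels in \[0, 1\];
#'   fibrils must render darker than the background.
#' @param noise_sd Additive Gaussian noise SD (gray levels), applied after
#'   blurring and clipped to \[0, 1\].
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 disables blur).
#' @param seed Integer seed; the generator is bit-reproducible for a fixed
#'   seed, or `NULL` to use the current RNG state.
#' @return An object of class `fibril_field_params`.
#' @export
fibril_field_params <- function(target_density = 60,
                                diameter_mean_nm = 28,
                                diameter_sd_nm = 4,
                                diameter_law = c("lognormal", "truncated-normal"),
                                min_gap_nm = 6,
                                field_width_px = 1024L,
                                field_height_px = 1024L,
                                pixel_size_nm = 2,
                                fibril_intensity = 0.2,
                                background_intensity = 0.75,
                                noise_sd = 0.05,
                                blur_sigma_px = 0.8,
                                seed = NULL) {
  diameter_law <- match.arg(diameter_law)
  if (!is.numeric(target_density) || target_density < 0)
    stop("`target_density` must be >= 0", call. = FALSE)
  for (nm in c("diameter_mean_nm", "diameter_sd_nm", "pixel_size_nm"))
    stop_if_not_scalar_pos(get(nm), nm)
  if (min_gap_nm < 0) stop("`min_gap_nm` must be >= 0", call. = FALSE)
  if (field_width_px < 1 || field_height_px < 1)
    stop("field dimensions must be positive", call. = FALSE)
  if (fibril_intensity >= background_intensity)
    stop("`fibril_intensity` must be below `background_intensity`: ",
         "fibril cross-sections render dark on a brighter background",
         call. = FALSE)
  if (noise_sd < 0 || blur_sigma_px < 0)
    stop("`noise_sd` and `blur_sigma_px` must be >= 0", call. = FALSE)
  packing <- target_density * pi / 4 *
    (diameter_mean_nm + min_gap_nm)^2 * 1e-6
  if (packing >= 0.55)
    stop(sprintf(paste0(
      "infeasible packing: target_density * pi/4 * (diameter_mean_nm + ",
      "min_gap_nm)^2 * 1e-6 = %.3f must be < 0.55"), packing), call. = FALSE)
  structure(list(
    target_density = target_density,
    diameter_mean_nm = diameter_mean_nm, diameter_sd_nm = diameter_sd_nm,
    diameter_law = diameter_law, min_gap_nm = min_gap_nm,
    field_width_px = as.integer(field_width_px),
    field_height_px = as.integer(field_height_px),
    pixel_size_nm = pixel_size_nm,
    fibril_intensity = fibril_intensity,
    background_intensity = background_intensity,
    noise_sd = noise_sd, blur_sigma_px = blur_sigma_px, seed = seed),
    class = "fibril_field_params")
}

draw_diameters <- function(n, params) {
  m <- params$diameter_mean_nm
  s <- params$diameter_sd_nm
  if (params$diameter_law == "lognormal") {
    sdlog <- sqrt(log1p((s / m)^2))
    meanlog <- log(m) - sdlog^2 / 2
    rlnorm(n, meanlog, sdlog)
  } else {
    # inverse-CDF truncation at 0: one uniform per draw, exact
    p0 <- pnorm(0, m, s)
    qnorm(runif(n, p0, 1), m, s)
  }
}

#' Generate a hard-core fibril field and its TEM-like raster image
#'
#' Places fibril cross-sections by random sequential adsorption: diameters
#' are drawn from the configured law, candidate centers uniformly on the
#' field, and a candidate is accepted only if its edge-to-edge distance to
#' every accepted fibril is at least `min_gap_nm`. Placement stops when the
#' realized density reaches the target or when the attempt budget (100 times
#' the target count) is exhausted, the latter being an error. The accepted
#' disks are rendered with area-weighted anti-aliasing at boundary pixels,
#' blurred, and degraded with additive Gaussian noise clipped to \[0, 1\].
#'
#' @param params A [fibril_field_params()] object.
#' @return A list of class `fibril_field` with elements `centers_nm`
#'   (two-column matrix, x then y), `diameters_nm`, `realized_density`
#'   (fibrils per square micrometre, exactly count / field area), `params`,
#'   and `image` (numeric matrix in \[0, 1\], `field_height_px` rows).
#' @export
generate_fibril_field <- function(params) {
  stopifnot(inherits(params, "fibril_field_params"))
  w_nm <- params$field_width_px * params$pixel_size_nm
  h_nm <- params$field_height_px * params$pixel_size_nm
  area_um2 <- (w_nm / 1000) * (h_nm / 1000)
  n_target <- ceiling(params$target_density * area_um2)

  with_seed_(params$seed, {
    if (n_target == 0) {
      centers <- matrix(numeric(0), ncol = 2,
                        dimnames = list(NULL, c("x_nm", "y_nm")))
      diam <- numeric(0)
    } else {
      pool <- draw_diameters(100 * n_target, params)
      placed <- rsa_place(n_target, pool, w_nm, h_nm, params$min_gap_nm)
      if (length(placed$d_nm) < n_target)
        stop(sprintf(paste0(
          "hard-core placement exhausted its attempt budget: realized ",
          "density %.2f of target %.2f fibrils/um^2"),
          length(placed$d_nm) / area_um2, params$target_density),
          call. = FALSE)
      centers <- cbind(x_nm = placed$x_nm, y_nm = placed$y_nm)
      diam <- placed$d_nm
    }
    img <- render_field_image(centers, diam, params)
    structure(list(centers_nm = centers, diameters_nm = diam,
                   realized_density = nrow(centers) / area_um2,
                   params = params, image = img),
              class = "fibril_field")
  })
}

# Raster a placed field: disks -> blur -> noise -> clip. x maps to columns,
# y to rows; pixel (r, c) covers [r, r+1) x [c, c+1) in pixel units.
render_field_image <- function(centers, diameters_nm, params) {
  ps <- params$pixel_size_nm
  img <- render_disks(params$field_height_px, params$field_width_px,
                      centers[, "y_nm"] / ps, centers[, "x_nm"] / ps,
                      diameters_nm / 2 / ps,
                      params$fibril_intensity, params$background_intensity,
                      supersample = 8L)
  if (params$blur_sigma_px > 0)
    img <- EBImage::gblur(img, sigma = params$blur_sigma_px)
  if (params$noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, params$noise_sd), nrow(img))
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' @export
print.fibril_field <- function(x, ...) {
  cat(sprintf(
    "<fibril_field> %d fibrils, %.2f /um^2 realized (target %.2f)\n",
    nrow(x$centers_nm), x$realized_density, x$params$target_density))
  cat(sprintf("  raster %d x %d px at %.3g nm/px\n",
              x$params$field_height_px, x$params$field_width_px,
              x$params$pixel_size_nm))
  invisible(x)
}
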