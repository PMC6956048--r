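#' Write a fibril field image with its truth sidecar
#'
#' Writes the raster as single-channel 16-bit TIFF or 8-bit PNG (chosen by
#' file extension) and a JSON sidecar `<path>.json` holding `pixel_size_nm`
#' and the full ground-truth record (centers, diameters, realized density).
#'
#' @param field A [generate_fibril_field()] result.
#' @param path Output image path ending in `.tiff`/`.tif` or `.png`.
#' @return `path`, invisibly.
#' @export
write_field_image <- function(field, path) {
  stopifnot(inherits(field, "fibril_field"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(field$image, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(field$image, path)
  } else stop("unsupported image extension: ", ext, call. = FALSE)
  sidecar <- list(
    pixel_size_nm = field$params$pixel_size_nm,
    realized_density = field$realized_density,
    centers_x_nm = field$centers_nm[, "x_nm"],
    centers_y_nm = field$centers_nm[, "y_nm"],
    diameters_nm = field$diameters_nm,
    params = field$params[setdiff(names(field$params), "seed")])
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fibril field image and its sidecar
#'
#' @param path Image path written by [write_field_image()].
#' @return List with `image` (numeric matrix in \[0, 1\]), `pixel_size_nm`,
#'   and `truth` (the sidecar contents) when the sidecar exists.
#' @export
read_field_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported image extension: ", ext, call. = FALSE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1)
      stop("`", path, "` is multi-channel; expected a single gray channel",
           call. = FALSE)
    img <- img[, , 1]
  }
  sc_path <- paste0(path, ".json")
  truth <- if (file.exists(sc_path)) jsonlite::read_json(sc_path,
                                                         simplifyVector = TRUE)
  list(image = img,
       pixel_size_nm = if (!is.null(truth)) truth$pixel_size_nm,
       truth = truth)
}

#' Write / read a tensile record as CSV
#'
#' Columns `time_s`, `displacement_mm`, `load_N`; the strip geometry goes
#' into a JSON sidecar `<path>.json` so the CSV schema stays minimal.
#'
#' @param record A [tensile_record()].
#' @param path Output CSV path.
#' @return `path` invisibly (writer); a `tensile_record` (reader).
#' @export
write_tensile_csv <- function(record, path) {
  stopifnot(inherits(record, "tensile_record"))
  write.csv(as.data.frame(record)[c("time_s", "displacement_mm", "load_N")],
            path, row.names = FALSE)
  jsonlite::write_json(
    list(strip_width_mm = attr(record, "strip_width_mm"),
         thickness_mm = attr(record, "thickness_mm"),
         gauge_length_mm = attr(record, "gauge_length_mm")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tensile_csv
#' @param strip_width_mm,thickness_mm,gauge_length_mm Geometry overrides;
#'   taken from the sidecar when `NULL`.
#' @export
read_tensile_csv <- function(path, strip_width_mm = NULL, thickness_mm = NULL,
                             gauge_length_mm = NULL) {
  d <- read.csv(path)
  sc_path <- paste0(path, ".json")
  sc <- if (file.exists(sc_path)) jsonlite::read_json(sc_path) else list()
  geom <- function(given, key) {
    if (!is.null(given)) given
    else if (!is.null(sc[[key]])) sc[[key]]
    else stop("`", key, "` not given and absent from sidecar", call. = FALSE)
  }
  tensile_record(d$time_s, d$displacement_mm, d$load_N,
                 geom(strip_width_mm, "strip_width_mm"),
                 geom(thickness_mm, "thickness_mm"),
                 geom(gauge_length_mm, "gauge_length_mm"))
}

#' Write / read a thermogram as CSV
#'
#' Columns `temperature_C`, `heat_flow_mW`.
#'
#' @param tg A [thermogram()].
#' @param path CSV path.
#' @return `path` invisibly (writer); a `thermogram` (reader).
#' @export
write_thermogram_csv <- function(tg, path) {
  stopifnot(inherits(tg, "thermogram"))
  write.csv(as.data.frame(tg), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thermogram_csv
#' @export
read_thermogram_csv <- function(path) {
  d <- read.csv(path)
  thermogram(d$temperature_C, d$heat_flow_mW)
}

#' Write / read a qPCR Ct table as CSV
#'
#' Columns `sample_id`, `group`, `gene`, `ct` (long format).
#'
#' @param table A `ct_table` data frame.
#' @param path CSV path.
#' @return `path` invisibly (writer); a `ct_table` (reader).
#' @export
write_ct_csv <- function(table, path) {
  stopifnot(is.data.frame(table),
            all(c("sample_id", "group", "gene", "ct") %in% names(table)))
  write.csv(as.data.frame(table)[c("sample_id", "group", "gene", "ct")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_csv
#' @export
read_ct_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "group", "gene", "ct") %in% names(d)))
  class(d) <- c("ct_table", "data.frame")
  d
}

#' Write detections as CSV
#'
#' One row per detected fibril with the columns of `fibril_detections`.
#'
#' @param detections A `fibril_detections` data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, path) {
  write.csv(as.data.frame(detections), path, row.names = FALSE)
  invisible(path)
}
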