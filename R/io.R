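#' Write / read a complex frame series container
#'
#' The series is stored as a directory container: `frames.feather` holds
#' the real and imaginary parts as lossless double columns (Arrow Feather)
#' and `meta.json` carries the array dimensions and all optical metadata
#' (wavelength, refractive index, pixel sizes, silicone geometry, ...).
#' The round trip is bit-exact for data and metadata.
#'
#' @param series A `"coce_series"`.
#' @param path Container directory (created if missing).
#' @return `write_series()` returns `path` invisibly; `read_series()`
#'   returns a `"coce_series"`.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "coce_series"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arrow::write_feather(
    data.frame(re = as.vector(Re(series$data)),
               im = as.vector(Im(series$data))),
    file.path(path, "frames.feather"))
  meta <- series[setdiff(names(series), "data")]
  meta$dim <- dim(series$data)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  fpath <- file.path(path, "frames.feather")
  mpath <- file.path(path, "meta.json")
  if (!file.exists(fpath)) coce_stop("container %s lacks frames.feather", path)
  if (!file.exists(mpath)) coce_stop("container %s lacks meta.json", path)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  required <- c("dim", "wavelength_um", "refractive_index",
                "axial_pixel_um", "lateral_pixel_um")
  for (k in required)
    if (is.null(meta[[k]]))
      coce_stop("series metadata is missing attribute '%s'", k)
  df <- arrow::read_feather(fpath)
  dims <- as.integer(meta$dim)
  if (nrow(df) != prod(dims))
    coce_stop("frame data length %d does not match dimensions %s",
              nrow(df), paste(dims, collapse = "x"))
  out <- meta[setdiff(names(meta), "dim")]
  out$data <- array(complex(real = df$re, imaginary = df$im), dim = dims)
  structure(out, class = "coce_series")
}

#' Write / read a float map as TIFF with a JSON sidecar
#'
#' Stiffness and strain maps export as 32-bit float TIFF. The TIFF sample
#' range is `[0, 1]`, so values are stored divided by a scale factor
#' recorded in the sidecar (default: the map maximum); invalid pixels are
#' written as the sidecar's `na_value`. The sidecar also carries units and
#' acquisition context.
#'
#' @param map A `"coce_stiffness"`.
#' @param path Output `.tif` path; the sidecar is `<path>.json`.
#' @param scale Normalization constant; defaults to the finite maximum.
#' @return `write_stiffness_tiff()` returns `path` invisibly;
#'   `read_stiffness_tiff()` returns a `"coce_stiffness"` (values at
#'   float32 precision).
#' @export
write_stiffness_tiff <- function(map, path, scale = NULL) {
  stopifnot(inherits(map, "coce_stiffness"))
  v <- map$values
  if (is.null(scale)) scale <- max(v[is.finite(v)], 1)
  img <- v / scale
  img[!is.finite(img)] <- 0
  tiff::writeTIFF(img, path, bits.per.sample = 32L)
  mask_path <- sub("\\.tiff?$", "_mask.png", path)
  png::writePNG(matrix(as.numeric(map$signal_mask), nrow(v), ncol(v)),
                mask_path)
  jsonlite::write_json(
    list(scale_kPa = scale, na_value = 0, units = "kPa",
         axial_pixel_um = map$axial_pixel_um,
         lateral_pixel_um = map$lateral_pixel_um,
         silicone_px = map$silicone_px,
         standardized_stress_kPa = map$standardized_stress_kPa,
         stress_window_kPa = map$stress_window_kPa,
         mask_file = basename(mask_path)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stiffness_tiff
#' @export
read_stiffness_tiff <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) coce_stop("missing sidecar %s", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  mask_path <- file.path(dirname(path), meta$mask_file)
  mask <- png::readPNG(mask_path) > 0.5
  new_stiffness(img * meta$scale_kPa, mask,
                meta$axial_pixel_um, meta$lateral_pixel_um,
                meta$silicone_px, meta$standardized_stress_kPa,
                meta$stress_window_kPa)
}

CLASS_COLORS <- c(NON_SIGNAL = "#FFFFFF", LOW = "#d7301f",
                  STROMA = "#fc8d59", CANCER_GLAND = "#40E0D0",
                  VERY_HIGH = "#2b4fbe")

#' Write a segmented class map as an 8-bit PNG
#'
#' Fixed legend: white = non-signal, warm reds = low-stiffness tissue and
#' stroma, turquoise = glandular cancer (520-950 kPa), blue = very high
#' stiffness (>950 kPa).
#'
#' @param class_map A [classify_pixels()] result.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_classmap_png <- function(class_map, path) {
  stopifnot(inherits(class_map, "coce_classmap"))
  cls <- class_map$classes
  rgb <- grDevices::col2rgb(CLASS_COLORS) / 255
  img <- array(0, dim = c(nrow(cls), ncol(cls), 3L))
  for (k in seq_along(CLASS_COLORS)) {
    sel <- cls == (k - 1L)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- rgb[ch, k]
      img[, , ch] <- plane
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Per-sample segmentation report as JSON
#'
#' Machine-readable record of the feature vector, subtype call and cancer
#' area for one segmented sample, including the class thresholds used so
#' every call is auditable.
#'
#' @param segmentation A [coce_segment()] result.
#' @param path Output `.json` path.
#' @param ranges The [class_ranges()] used (recorded for audit).
#' @return `path`, invisibly.
#' @export
write_segmentation_json <- function(segmentation, path,
                                    ranges = class_ranges()) {
  stopifnot(inherits(segmentation, "coce_segmentation"))
  jsonlite::write_json(
    list(call = segmentation$call,
         features = segmentation$features,
         cancer_area_percent = segmentation$cancer_area_percent,
         class_ranges = unclass(ranges)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
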