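#' Mechanical tissue class for phantom construction
#'
#' Describes one mechanical/optical tissue class used by the phantom
#' generator. The tangent Young's modulus follows the affine stiffening law
#' \eqn{E_t(\sigma) = E_0 + \beta \sigma}, the simplest form capturing the
#' pronounced nonlinearity of soft-tissue stress-strain curves; `beta = 0`
#' gives a linear (Hookean) material. Non-signal classes (extracellular
#' mucin, wide gland lumina) deform mechanically but backscatter essentially
#' no light, so their pixels carry noise only.
#'
#' @param label Small positive integer id, unique within a phantom.
#' @param name Human-readable class name.
#' @param E0 Tangent Young's modulus at zero stress, kPa. Must be positive
#'   (non-signal material is typically soft but still finite, e.g. mucin).
#' @param beta Dimensionless stiffening rate; tangent modulus at stress
#'   \eqn{\sigma} is `E0 + beta * sigma`. Must be non-negative.
#' @param scatter_amp Relative backscatter amplitude in `[0, 1]`.
#' @param is_nonsignal Logical; `TRUE` for mucin/lumen classes that produce
#'   no usable OCT signal (`scatter_amp` is forced to 0).
#' @return An object of class `"mechanical_class"`.
#' @examples
#' mechanical_class(1L, "stroma", E0 = 295, beta = 3)
#' mechanical_class(2L, "mucin", E0 = 30, is_nonsignal = TRUE)
#' @export
mechanical_class <- function(label, name, E0, beta = 0, scatter_amp = 1,
                             is_nonsignal = FALSE) {
  if (!is_scalar_num(label) || label < 1 || label != round(label))
    coce_stop("'label' must be a positive integer")
  if (!is_scalar_num(E0) || E0 <= 0)
    coce_stop("class '%s': E0 must be > 0 kPa (got %s)", name, format(E0))
  if (!is_scalar_num(beta) || beta < 0)
    coce_stop("class '%s': beta must be >= 0", name)
  if (!is_scalar_num(scatter_amp) || scatter_amp < 0 || scatter_amp > 1)
    coce_stop("class '%s': scatter_amp must lie in [0, 1]", name)
  if (isTRUE(is_nonsignal)) scatter_amp <- 0
  structure(
    list(label = as.integer(label), name = as.character(name), E0 = E0,
         beta = beta, scatter_amp = scatter_amp,
         is_nonsignal = isTRUE(is_nonsignal)),
    class = "mechanical_class")
}

#' Geometric primitives for phantom construction
#'
#' Shapes are placed in physical tissue coordinates: `x` in micrometres from
#' the left image edge, `z` in micrometres downward from the silicone-tissue
#' interface. Later shapes overwrite earlier ones during rasterization.
#'
#' @param cx_um,cz_um Centre coordinates, micrometres.
#' @param width_um,height_um Rectangle extents, micrometres.
#' @param rx_um,rz_um Ellipse semi-axes (lateral, axial), micrometres.
#' @param class Integer label of a [mechanical_class()] declared in the
#'   [phantom_spec()].
#' @return A shape description list consumed by [build_phantom()].
#' @export
shape_rect <- function(cx_um, cz_um, width_um, height_um, class) {
  if (width_um <= 0 || height_um <= 0)
    coce_stop("rectangle has zero or negative area (%g x %g um)",
              width_um, height_um)
  list(type = "rect", cx = cx_um, cz = cz_um, w = width_um, h = height_um,
       class = as.integer(class))
}

#' @rdname shape_rect
#' @export
shape_ellipse <- function(cx_um, cz_um, rx_um, rz_um, class) {
  if (rx_um <= 0 || rz_um <= 0)
    coce_stop("ellipse has zero or negative area (semi-axes %g x %g um)",
              rx_um, rz_um)
  list(type = "ellipse", cx = cx_um, cz = cz_um, rx = rx_um, rz = rz_um,
       class = as.integer(class))
}

#' Phantom specification: geometry, sampling and mechanical classes
#'
#' Defines a silicone-tissue "sandwich" as imaged by the OCT probe: a
#' linearly elastic pre-calibrated reference silicone layer occupies the
#' topmost rows, and the tissue below is filled with a background class plus
#' arbitrary labelled shapes. The total imaged depth must not exceed
#' 2000 um (the instrument scans at most ~1.5-2 mm).
#'
#' @param depth_px,lateral_px Grid size in pixels (depth includes the
#'   silicone rows).
#' @param axial_pixel_um,lateral_pixel_um Pixel pitch, micrometres. The
#'   axial default of 4 um oversamples the 15 um axial point-spread
#'   function.
#' @param silicone_thickness_um Reference silicone layer thickness, um.
#' @param E_sil Silicone Young's modulus, kPa (linear material).
#' @param refractive_index Tissue group refractive index `n`; converts
#'   optical phase to physical displacement. Default 1.4 (typical soft
#'   tissue).
#' @param background Integer label of the tissue background class.
#' @param classes List of [mechanical_class()] objects (tissue classes; the
#'   silicone layer is described by `E_sil` and does not need a class).
#' @param shapes List of [shape_rect()] / [shape_ellipse()] primitives.
#' @return An object of class `"phantom_spec"`.
#' @examples
#' spec <- phantom_spec(
#'   depth_px = 150, lateral_px = 64, silicone_thickness_um = 200,
#'   classes = list(mechanical_class(1, "mucosa", E0 = 58)),
#'   background = 1)
#' @export
phantom_spec <- function(depth_px = 500L, lateral_px = 512L,
                         axial_pixel_um = 4, lateral_pixel_um = 4,
                         silicone_thickness_um = 300, E_sil = 100,
                         refractive_index = 1.4,
                         background = 1L, classes = list(), shapes = list()) {
  if (depth_px < 2 || lateral_px < 1)
    coce_stop("grid must be at least 2 x 1 pixels")
  if (axial_pixel_um <= 0 || lateral_pixel_um <= 0)
    coce_stop("pixel sizes must be positive")
  if (depth_px * axial_pixel_um > 2000)
    coce_stop("total imaged depth %g um exceeds the 2000 um scanning depth",
              depth_px * axial_pixel_um)
  if (E_sil <= 0) coce_stop("E_sil must be positive")
  if (refractive_index <= 0) coce_stop("refractive_index must be positive")
  sil_px <- as.integer(round(silicone_thickness_um / axial_pixel_um))
  if (sil_px < 1 || sil_px >= depth_px)
    coce_stop("silicone layer (%d px) must occupy at least one row and leave tissue below",
              sil_px)
  if (length(classes) == 0)
    coce_stop("at least one mechanical class is required")
  labels <- vapply(classes, function(cl) cl$label, integer(1))
  if (anyDuplicated(labels))
    coce_stop("mechanical class labels must be unique")
  if (!background %in% labels)
    coce_stop("background label %d is not among the declared classes", background)
  for (sh in shapes) {
    if (!sh$class %in% labels)
      coce_stop("shape refers to undeclared class label %d", sh$class)
  }
  structure(
    list(depth_px = as.integer(depth_px), lateral_px = as.integer(lateral_px),
         axial_pixel_um = axial_pixel_um, lateral_pixel_um = lateral_pixel_um,
         silicone_thickness_um = silicone_thickness_um,
         silicone_px = sil_px, E_sil = E_sil,
         refractive_index = refractive_index,
         background = as.integer(background),
         classes = classes, shapes = shapes),
    class = "phantom_spec")
}

#' Rasterize a phantom specification
#'
#' Deterministically rasterizes the phantom geometry onto the pixel grid:
#' silicone occupies the topmost rows (label 0), the tissue background fills
#' the rest, and shapes are painted in list order (later shapes overwrite
#' earlier ones). A pixel belongs to a shape when its centre lies inside the
#' primitive.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `"coce_phantom"`: the label map plus per-pixel
#'   `E0`, `beta`, `scatter_amp` and `is_nonsignal` matrices (silicone rows
#'   carry `E_sil` and full scattering amplitude).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  D <- spec$depth_px; W <- spec$lateral_px; s <- spec$silicone_px
  Dt <- D - s
  x_um <- (seq_len(W) - 0.5) * spec$lateral_pixel_um
  z_um <- (seq_len(Dt) - 0.5) * spec$axial_pixel_um  # from the interface down
  width_um <- W * spec$lateral_pixel_um
  depth_um <- Dt * spec$axial_pixel_um

  tissue <- matrix(spec$background, Dt, W)
  for (k in seq_along(spec$shapes)) {
    sh <- spec$shapes[[k]]
    inside <- if (sh$type == "rect") {
      outer(abs(z_um - sh$cz) <= sh$h / 2, abs(x_um - sh$cx) <= sh$w / 2, "&")
    } else {
      outer((z_um - sh$cz)^2 / sh$rz^2, (x_um - sh$cx)^2 / sh$rx^2, "+") <= 1
    }
    if (!any(inside))
      coce_stop("shape %d (%s, class %d) lies outside the %g x %g um tissue grid",
                k, sh$type, sh$class, width_um, depth_um)
    tissue[inside] <- sh$class
  }

  label_map <- rbind(matrix(0L, s, W), tissue)
  E0 <- matrix(spec$E_sil, D, W)
  beta <- matrix(0, D, W)
  amp <- matrix(1, D, W)
  nonsig <- matrix(FALSE, D, W)
  for (cl in spec$classes) {
    idx <- which(label_map == cl$label)
    E0[idx] <- cl$E0
    beta[idx] <- cl$beta
    amp[idx] <- cl$scatter_amp
    nonsig[idx] <- cl$is_nonsignal
  }
  structure(
    list(label_map = label_map, E0 = E0, beta = beta, scatter_amp = amp,
         is_nonsignal = nonsig, spec = spec),
    class = "coce_phantom")
}

#' @export
print.coce_phantom <- function(x, ...) {
  sp <- x$spec
  cat(sprintf("C-OCE phantom: %d x %d px (%.0f x %.0f um), silicone %d rows (E_sil = %g kPa)\n",
              sp$depth_px, sp$lateral_px,
              sp$depth_px * sp$axial_pixel_um,
              sp$lateral_px * sp$lateral_pixel_um,
              sp$silicone_px, sp$E_sil))
  for (cl in sp$classes) {
    n <- sum(x$label_map == cl$label)
    cat(sprintf("  class %d '%s': E0 = %g kPa, beta = %g, %d px%s\n",
                cl$label, cl$name, cl$E0, cl$beta, n,
                if (cl$is_nonsignal) " (non-signal)" else ""))
  }
  invisible(x)
}
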