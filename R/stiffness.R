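#' Construct a stiffness map object
#'
#' Wraps a tangent Young's modulus matrix (kPa) and its signal mask as a
#' `"coce_stiffness"`, e.g. for segmenting maps produced outside the
#' package or ground-truth maps.
#'
#' @param values Numeric matrix, kPa (depth x lateral).
#' @param mask Logical matrix: `TRUE` where the map carries signal.
#' @param axial_pixel_um,lateral_pixel_um Pixel pitch, um.
#' @param silicone_px Topmost rows occupied by the reference silicone
#'   (0 for a tissue-only map).
#' @param standardized_stress_kPa,stress_window_kPa Loading conditions the
#'   map refers to.
#' @return A `"coce_stiffness"` object.
#' @export
stiffness_map <- function(values, mask = is.finite(values),
                          axial_pixel_um = 4, lateral_pixel_um = 4,
                          silicone_px = 0L, standardized_stress_kPa = 4,
                          stress_window_kPa = c(3, 5)) {
  stopifnot(is.matrix(values), identical(dim(values), dim(mask)))
  new_stiffness(values, mask, axial_pixel_um, lateral_pixel_um,
                silicone_px, standardized_stress_kPa, stress_window_kPa)
}

new_stiffness <- function(values, mask, axial_pixel_um, lateral_pixel_um,
                          silicone_px, standardized_stress_kPa = 4,
                          stress_window_kPa = c(3, 5)) {
  values[!mask] <- NA_real_
  structure(
    list(values = values, signal_mask = mask,
         axial_pixel_um = axial_pixel_um, lateral_pixel_um = lateral_pixel_um,
         silicone_px = as.integer(silicone_px),
         standardized_stress_kPa = standardized_stress_kPa,
         stress_window_kPa = stress_window_kPa),
    class = "coce_stiffness")
}

#' Applied stress from the reference silicone layer
#'
#' The pre-calibrated silicone is highly linear, so its cumulative strain is
#' proportional to the stress compressing the sandwich:
#' \eqn{\sigma = E_{sil}\,\varepsilon_{sil}}. Stress is estimated per
#' lateral column (a simplified local-stress standardization; set
#' `mode = "global"` for a single frame-wide value) by averaging the valid
#' cumulative silicone strain in each column, excluding a margin above the
#' silicone-tissue interface where window averaging mixes in tissue strain.
#'
#' @param cumulative List of cumulative `"coce_strain"` fields (one per
#'   frame pair), e.g. `estimate_strains(series)$cumulative`.
#' @param silicone_px Number of topmost rows occupied by silicone.
#' @param E_sil Silicone Young's modulus, kPa.
#' @param mode `"column"` (default) or `"global"`.
#' @param margin_px Rows above the interface excluded from averaging;
#'   default half the axial window plus the lag, taken from the fields.
#' @return Matrix `frames x lateral` of applied stress, kPa (for
#'   `mode = "global"` every column carries the same value). The first
#'   frame pair already includes the first stress increment; a leading zero
#'   row is prepended so row `f` is the stress at frame `f` of the series.
#' @export
silicone_stress <- function(cumulative, silicone_px, E_sil,
                            mode = c("column", "global"), margin_px = NULL) {
  mode <- match.arg(mode)
  if (length(cumulative) == 0) coce_stop("no cumulative strain fields")
  f1 <- cumulative[[1]]
  if (is.null(margin_px)) {
    wa <- window_px(f1$window_axial_um, f1$meta$axial_pixel_um %||% 1)
    margin_px <- ceiling(wa / 2) + f1$axial_lag_px
  }
  rows <- seq_len(max(silicone_px - margin_px, 0L))
  if (length(rows) < 2)
    coce_stop("silicone layer too thin (%d px) for a %d px processing margin",
              silicone_px, margin_px)
  W <- ncol(f1$values)
  nf <- length(cumulative)
  sig <- matrix(0, nf + 1L, W)
  for (f in seq_len(nf)) {
    v <- cumulative[[f]]$values[rows, , drop = FALSE]
    m <- cumulative[[f]]$valid_mask[rows, , drop = FALSE]
    nvalid <- colSums(m)
    if (any(nvalid < 0.5 * length(rows)))
      coce_stop("silicone region invalid in %d column(s) at frame pair %d",
                sum(nvalid < 0.5 * length(rows)), f)
    colmean <- colSums(ifelse(m, v, 0)) / nvalid
    sig[f + 1L, ] <- E_sil * if (mode == "global") mean(colmean) else colmean
  }
  sig
}

#' Spatially resolved stress-strain records
#'
#' Pairs the per-pixel cumulative tissue strain with the silicone-derived
#' applied stress at every frame, producing the per-pixel stress-strain
#' dependence from which tangent moduli are read. Pixels whose strain
#' estimate is invalid in more than `max_invalid_fraction` of the frame
#' pairs are masked.
#'
#' @param cumulative List of cumulative `"coce_strain"` fields.
#' @param sigma Stress schedule from [silicone_stress()]
#'   (`(frames+1) x lateral`, kPa, starting at 0).
#' @param max_invalid_fraction Maximum tolerated fraction of invalid frames
#'   per pixel (default 0.3).
#' @param monotone_tol_kPa Tolerated non-monotonicity in the stress
#'   schedule before an error is raised (default 2% of the maximum stress);
#'   small noise dips are repaired by a running maximum.
#' @return Object of class `"coce_ssgrid"`: strain array
#'   `(frames+1) x depth x lateral` (leading zero plane), stress matrix,
#'   validity mask and metadata.
#' @export
build_stress_strain <- function(cumulative, sigma,
                                max_invalid_fraction = 0.3,
                                monotone_tol_kPa = NULL) {
  f1 <- cumulative[[1]]
  D <- nrow(f1$values); W <- ncol(f1$values)
  nf <- length(cumulative)
  if (!identical(dim(sigma), c(nf + 1L, W)))
    coce_stop("stress schedule shape %s does not match %d frame pairs x %d columns",
              paste(dim(sigma), collapse = "x"), nf, W)
  if (is.null(monotone_tol_kPa)) monotone_tol_kPa <- 0.02 * max(sigma)
  drops <- apply(sigma, 2L, function(s) -min(diff(s), 0))
  if (any(drops > monotone_tol_kPa))
    coce_stop(paste0("stress schedule decreases by %.3g kPa (tolerance %.3g); ",
                     "silicone strain tracking failed"),
              max(drops), monotone_tol_kPa)
  sigma <- apply(sigma, 2L, cummax)

  eps <- array(0, dim = c(nf + 1L, D, W))
  invalid <- matrix(0L, D, W)
  for (f in seq_len(nf)) {
    v <- cumulative[[f]]$values
    m <- cumulative[[f]]$valid_mask
    v[!m] <- NA_real_
    eps[f + 1L, , ] <- v
    invalid <- invalid + !m
  }
  mask <- (invalid / nf) <= max_invalid_fraction
  meta <- f1$meta
  structure(
    list(eps = eps, sigma = sigma, mask = mask,
         axial_pixel_um = meta$axial_pixel_um,
         lateral_pixel_um = meta$lateral_pixel_um,
         silicone_px = meta$silicone_px, E_sil = meta$E_sil),
    class = "coce_ssgrid")
}

#' Tangent Young's modulus map at the standardized stress
#'
#' For every pixel the tangent modulus is the secant slope
#' \eqn{E_t = \Delta\sigma / \Delta\varepsilon} of its stress-strain record
#' between the stresses where the schedule crosses the window endpoints
#' (default 3 and 5 kPa, centred on the standardized 4 kPa), with linear
#' interpolation in stress between frames. Pixels with non-increasing
#' strain, too many invalid frames, or implausibly large moduli
#' (> `max_modulus_kPa`, far beyond any stiffness observed in colorectal
#' tissue) are masked as non-signal.
#'
#' @param grid A [build_stress_strain()] result.
#' @param stress_window_kPa Two-element stress window, kPa.
#' @param standardized_stress_kPa Reporting stress (must lie inside the
#'   window).
#' @param max_modulus_kPa Artifact clamp (default 5000).
#' @return A `"coce_stiffness"` object: tangent modulus (kPa) and signal
#'   mask.
#' @export
tangent_modulus_map <- function(grid, stress_window_kPa = c(3, 5),
                                standardized_stress_kPa = 4,
                                max_modulus_kPa = 5000) {
  stopifnot(inherits(grid, "coce_ssgrid"))
  lo <- stress_window_kPa[1]; hi <- stress_window_kPa[2]
  if (!(lo < standardized_stress_kPa && standardized_stress_kPa < hi))
    coce_stop("standardized stress must lie inside the stress window")
  nf <- nrow(grid$sigma); D <- dim(grid$eps)[2]; W <- dim(grid$eps)[3]
  if (any(grid$sigma[nf, ] < hi))
    coce_stop("insufficient compression: max stress %.2f kPa < %.2f kPa window edge",
              min(grid$sigma[nf, ]), hi)

  # strain at a given stress level, linearly interpolated in sigma per column
  eps_at <- function(level) {
    out <- matrix(NA_real_, D, W)
    for (x in seq_len(W)) {
      s <- grid$sigma[, x]
      f <- findInterval(level, s)          # last frame with s <= level
      if (f >= nf) f <- nf - 1L
      w <- if (s[f + 1L] > s[f]) (level - s[f]) / (s[f + 1L] - s[f]) else 0
      out[, x] <- (1 - w) * grid$eps[f, , x] + w * grid$eps[f + 1L, , x]
    }
    out
  }
  e_lo <- eps_at(lo)
  e_hi <- eps_at(hi)
  deps <- e_hi - e_lo
  Et <- (hi - lo) / deps
  ok <- grid$mask & is.finite(deps) & deps > 0 &
    is.finite(Et) & Et <= max_modulus_kPa
  new_stiffness(Et, ok, grid$axial_pixel_um, grid$lateral_pixel_um,
                grid$silicone_px %||% 0L, standardized_stress_kPa,
                stress_window_kPa)
}

#' Auto-detect the reference silicone band
#'
#' When the silicone thickness is not recorded in the series metadata, the
#' topmost contiguous band whose cumulative strain is depth-uniform (row
#' medians within `tol` of the top of the image) is taken as silicone:
#' inside the homogeneous reference layer the strain does not vary with
#' depth, while the silicone-tissue interface introduces a strain jump.
#'
#' @param cumulative List of cumulative strain fields; the final (largest
#'   strain) field is used.
#' @param tol Relative tolerance (default 0.02).
#' @return Estimated silicone thickness in rows.
#' @export
detect_silicone <- function(cumulative, tol = 0.02) {
  last <- cumulative[[length(cumulative)]]
  v <- last$values
  v[!last$valid_mask] <- NA_real_
  med <- apply(v, 1L, stats::median, na.rm = TRUE)
  ref <- stats::median(med[seq_len(max(3L, min(5L, length(med))))], na.rm = TRUE)
  if (!is.finite(ref) || ref == 0)
    coce_stop("cannot detect silicone: top rows carry no valid strain")
  bad <- which(abs(med - ref) > tol * abs(ref))
  if (length(bad) == 0)
    coce_stop("cannot detect silicone: strain is depth-uniform everywhere")
  max(bad[1] - 1L, 1L)
}

#' Fit a tangent Young's modulus map to a compression frame series
#'
#' One-call estimator chaining the full reconstruction: interframe phase
#' fields, vector-method strain, cumulative strain, silicone stress
#' calibration, per-pixel stress-strain records and the tangent-modulus map
#' at the standardized stress. This is the package's central model fit; the
#' returned object has `print`, `summary`, `plot` and `coef` methods.
#'
#' @param series A `"coce_series"` (simulated or read from disk).
#' @param config A [coce_config()]; individual fields can be overridden via
#'   `...`.
#' @param ... Named [coce_config()] overrides.
#' @return Object of class `"coce_fit"` with components `stiffness`
#'   (`"coce_stiffness"`), `sigma` (stress schedule, kPa), `cumulative_strain`
#'   (final cumulative `"coce_strain"`), `silicone_px`, and `config`.
#' @examples
#' \donttest{
#' ph <- phantom_spec(depth_px = 150, lateral_px = 48,
#'                    lateral_pixel_um = 12, silicone_thickness_um = 200,
#'                    classes = list(mechanical_class(1, "stroma", 295)),
#'                    background = 1)
#' sim <- simulate_compression_series(ph, acquisition_spec(n_frames = 40,
#'                                    seed = 7))
#' fit <- coce_fit(sim$series)
#' summary(fit)
#' }
#' @export
coce_fit <- function(series, config = coce_config(), ...) {
  stopifnot(inherits(series, "coce_series"))
  config <- modify_config(config, ...)
  st <- estimate_strains(series,
                         window_axial_um = config$window_axial_um,
                         window_lateral_um = config$window_lateral_um,
                         axial_lag_px = config$axial_lag_px,
                         amp_floor = config$amp_floor)
  sil_px <- series$silicone_px %||% detect_silicone(st$cumulative)
  E_sil <- series$E_sil %||% config$E_sil
  sigma <- silicone_stress(st$cumulative, sil_px, E_sil,
                           mode = config$stress_mode)
  grid <- build_stress_strain(st$cumulative, sigma,
                              max_invalid_fraction = config$max_invalid_fraction)
  map <- tangent_modulus_map(grid,
                             stress_window_kPa = config$stress_window_kPa,
                             standardized_stress_kPa = config$standardized_stress_kPa,
                             max_modulus_kPa = config$max_modulus_kPa)
  structure(
    list(stiffness = map, sigma = sigma,
         cumulative_strain = st$cumulative[[length(st$cumulative)]],
         silicone_px = sil_px, E_sil = E_sil, config = config,
         call = match.call()),
    class = "coce_fit")
}

# mean over the tissue part of the signal mask, excluding rows within
# `margin_um` of the silicone-tissue interface (the map's resolution limit)
tissue_values <- function(map, margin_um = 50) {
  s <- map$silicone_px + ceiling(margin_um / map$axial_pixel_um)
  rows <- seq(s + 1L, nrow(map$values))
  v <- map$values[rows, , drop = FALSE]
  m <- map$signal_mask[rows, , drop = FALSE]
  v[m]
}

#' Mean tissue stiffness of a fitted map
#'
#' Mean tangent modulus over valid tissue pixels, excluding a margin below
#' the silicone-tissue interface equal to the map's spatial resolution
#' (half the processing window).
#'
#' @param map A `"coce_stiffness"` or `"coce_fit"`.
#' @param margin_um Interface exclusion margin, um (default 50).
#' @return Mean stiffness in kPa.
#' @export
tissue_mean_stiffness <- function(map, margin_um = 50) {
  if (inherits(map, "coce_fit")) map <- map$stiffness
  mean(tissue_values(map, margin_um))
}

#' @export
print.coce_fit <- function(x, ...) {
  cat("C-OCE tangent Young's modulus fit\n")
  cat(sprintf("  standardized stress %g kPa (window %g-%g kPa), silicone %d rows, E_sil %g kPa\n",
              x$stiffness$standardized_stress_kPa,
              x$stiffness$stress_window_kPa[1], x$stiffness$stress_window_kPa[2],
              x$silicone_px, x$E_sil))
  cat(sprintf("  tissue mean stiffness: %.1f kPa (%.1f%% of pixels valid)\n",
              tissue_mean_stiffness(x), 100 * mean(x$stiffness$signal_mask)))
  invisible(x)
}

#' @export
summary.coce_fit <- function(object, config = object$config, ...) {
  map <- object$stiffness
  seg <- coce_segment(map, config = config)
  v <- tissue_values(map)
  out <- list(stiffness = summarize_stat(v),
              segmentation = seg,
              cancer_area_percent = seg$cancer_area_percent)
  class(out) <- "summary.coce_fit"
  out
}

#' @export
print.summary.coce_fit <- function(x, ...) {
  cat("Tissue stiffness (kPa):", x$stiffness$text, "\n")
  print(x$segmentation)
  invisible(x)
}

#' @export
coef.coce_fit <- function(object, ...) {
  seg <- coce_segment(object$stiffness, config = object$config)
  cls <- seg$class_map$classes
  v <- object$stiffness$values
  tissue <- row(cls) > object$silicone_px
  vapply(c(LOW = 1, STROMA = 2, CANCER_GLAND = 3, VERY_HIGH = 4),
         function(k) {
           sel <- tissue & cls == k
           if (any(sel)) mean(v[sel], na.rm = TRUE) else NA_real_
         }, numeric(1))
}

#' @export
plot.coce_fit <- function(x, ...) plot(x$stiffness, ...)

#' Plot a stiffness map with the standard C-OCE palette
#'
#' Warm red tones for soft tissue (mucosa), turquoise/blue for stiff cancer
#' classes, white for non-signal pixels.
#'
#' @param x A `"coce_stiffness"`.
#' @param zlim Stiffness range mapped onto the palette, kPa.
#' @param ... Passed to [graphics::image()].
#' @export
plot.coce_stiffness <- function(x, zlim = c(0, 1500), ...) {
  pal <- grDevices::colorRampPalette(
    c("#7f0000", "#d7301f", "#fc8d59", "#fdcc8a", "#a8ddb5",
      "#40E0D0", "#2b8cbe", "#084081"))(256)
  v <- pmin(pmax(x$values, zlim[1]), zlim[2])
  v[!x$signal_mask] <- NA_real_
  D <- nrow(v); W <- ncol(v)
  graphics::image(x = (seq_len(W) - 0.5) * x$lateral_pixel_um,
                  y = (seq_len(D) - 0.5) * x$axial_pixel_um,
                  z = t(v)[, D:1], col = pal, zlim = zlim, useRaster = TRUE,
                  xlab = "lateral, um", ylab = "depth, um", ...)
  invisible(x)
}

#' @export
print.coce_stiffness <- function(x, ...) {
  cat(sprintf("Tangent Young's modulus map at %g kPa: %d x %d px, %.1f%% valid\n",
              x$standardized_stress_kPa, nrow(x$values), ncol(x$values),
              100 * mean(x$signal_mask)))
  if (any(x$signal_mask))
    cat(sprintf("  range %.0f-%.0f kPa\n", min(x$values, na.rm = TRUE),
                max(x$values, na.rm = TRUE)))
  invisible(x)
}
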