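#' Interframe complex field
#'
#' Pixelwise product \eqn{\mathrm{conj}(a)\, b} of two consecutive complex
#' frames. Its argument is the interframe phase variation
#' \eqn{\Delta\phi(z, x) \in (-\pi, \pi]}, proportional to the axial
#' displacement accumulated between the two acquisitions.
#'
#' @param frame_a,frame_b Complex matrices (depth x lateral) of identical
#'   shape.
#' @param meta Optional named list of optical metadata (`wavelength_um`,
#'   `refractive_index`, `axial_pixel_um`, ...) carried through to the
#'   strain estimator; [estimate_strains()] fills it from a series.
#' @return Object of class `"coce_iframe"`: complex matrix `field` plus
#'   metadata.
#' @export
interframe_field <- function(frame_a, frame_b, meta = list()) {
  if (!identical(dim(frame_a), dim(frame_b)))
    coce_stop("frame shapes differ: %s vs %s",
              paste(dim(frame_a), collapse = "x"),
              paste(dim(frame_b), collapse = "x"))
  structure(list(field = Conj(frame_a) * frame_b, meta = meta),
            class = "coce_iframe")
}

new_strain_field <- function(values, mask, window_axial_um, window_lateral_um,
                             axial_lag_px, kind, meta = list()) {
  values[!mask] <- NA_real_
  structure(
    list(values = values, valid_mask = mask,
         window_axial_um = window_axial_um,
         window_lateral_um = window_lateral_um,
         axial_lag_px = axial_lag_px, kind = kind, meta = meta),
    class = "coce_strain")
}

#' Vector-method interframe strain estimation
#'
#' Estimates the axial gradient of the interframe phase variation without
#' phase unwrapping. For each pixel the axial lag product
#' \eqn{P(z,x) = \mathrm{conj}(F(z,x))\, F(z + \ell, x)} of the interframe
#' field \eqn{F} is formed, the complex values are averaged over a
#' rectangular window ("vector" averaging — the phase is singled out last),
#' and the strain follows from the argument of the window mean:
#' \deqn{\varepsilon = \arg(\bar P)\, \lambda / (4\pi n\, \ell\, \Delta z).}
#' Because phase enters only through interframe *differences* over a short
#' lag, strains up to about 1% per frame pair are recovered even where the
#' raw phase map wraps across \eqn{\pi}. Compression is reported positive.
#'
#' Windows are truncated at image borders; a pixel is invalid when less
#' than half of its window is in-image, or when the magnitude of the window
#' mean falls below `amp_floor` times the window-averaged amplitude product
#' (incoherent noise — non-signal regions).
#'
#' @param ifield A [interframe_field()] result.
#' @param window_axial_um,window_lateral_um Averaging window, um (the
#'   instrument's practical range is 80-100 um; default 100).
#' @param axial_lag_px Axial lag \eqn{\ell} in pixels (>= 1; default 3).
#' @param amp_floor Validity floor on `|mean(P)| / mean(|P|)` (default 0.25).
#' @param wavelength_um,refractive_index,axial_pixel_um,lateral_pixel_um
#'   Optical metadata; taken from the interframe field when present.
#' @return A `"coce_strain"` object (kind `"interframe"`).
#' @export
vector_strain <- function(ifield, window_axial_um = 100,
                          window_lateral_um = 100, axial_lag_px = 3L,
                          amp_floor = 0.25,
                          wavelength_um = NULL, refractive_index = NULL,
                          axial_pixel_um = NULL, lateral_pixel_um = NULL) {
  stopifnot(inherits(ifield, "coce_iframe"))
  m <- ifield$meta
  wavelength_um <- wavelength_um %||% m$wavelength_um
  refractive_index <- refractive_index %||% m$refractive_index
  axial_pixel_um <- axial_pixel_um %||% m$axial_pixel_um
  lateral_pixel_um <- lateral_pixel_um %||% m$lateral_pixel_um
  if (is.null(wavelength_um) || is.null(refractive_index) ||
      is.null(axial_pixel_um) || is.null(lateral_pixel_um))
    coce_stop("optical metadata (wavelength, n, pixel sizes) is required")
  lag <- as.integer(axial_lag_px)
  if (lag < 1) coce_stop("axial_lag_px must be >= 1")

  F <- ifield$field
  D <- nrow(F); W <- ncol(F)
  wa <- window_px(window_axial_um, axial_pixel_um)
  wl <- window_px(window_lateral_um, lateral_pixel_um)
  if (wa < lag) coce_stop("axial window (%d px) must cover the lag (%d px)", wa, lag)
  if (wa > D || wl > W)
    coce_stop("averaging window (%d x %d px) larger than the %d x %d image",
              wa, wl, D, W)
  if (D <= lag) coce_stop("image too shallow for lag %d", lag)

  Dp <- D - lag
  P <- Conj(F[seq_len(Dp), , drop = FALSE]) * F[lag + seq_len(Dp), , drop = FALSE]
  A <- Mod(P)  # |F(z)| |F(z+lag)|

  sum_re <- box_sum(Re(P), wa, wl)
  sum_im <- box_sum(Im(P), wa, wl)
  sum_amp <- box_sum(A, wa, wl)
  cnt <- box_count(Dp, W, wa, wl)

  pbar_mod <- sqrt(sum_re^2 + sum_im^2)
  phase <- atan2(sum_im, sum_re)
  eps <- phase * wavelength_um /
    (4 * pi * refractive_index * lag * axial_pixel_um)

  valid <- (pbar_mod >= amp_floor * sum_amp) & (cnt >= 0.5 * wa * wl)

  values <- matrix(NA_real_, D, W)
  mask <- matrix(FALSE, D, W)
  values[seq_len(Dp), ] <- eps
  mask[seq_len(Dp), ] <- valid
  new_strain_field(values, mask, window_axial_um, window_lateral_um, lag,
                   "interframe",
                   meta = list(wavelength_um = wavelength_um,
                               refractive_index = refractive_index,
                               axial_pixel_um = axial_pixel_um,
                               lateral_pixel_um = lateral_pixel_um,
                               silicone_px = m$silicone_px,
                               E_sil = m$E_sil))
}

#' Accumulate interframe strain fields
#'
#' Running pixelwise sum of a sequence of interframe strain fields,
#' yielding the cumulative strain at each frame of a compression series.
#' Summing several tens of small increments improves the strain
#' signal-to-noise ratio: increment errors add incoherently while the
#' strain adds linearly. The validity mask of each cumulative field is the
#' conjunction of all contributing interframe masks.
#'
#' @param fields List of `"coce_strain"` objects of kind `"interframe"`,
#'   identical shapes.
#' @return List of `"coce_strain"` objects of kind `"cumulative"`, one per
#'   input (the k-th is the sum of the first k increments).
#' @export
cumulate <- function(fields) {
  if (length(fields) == 0) coce_stop("no strain fields to accumulate")
  kinds <- vapply(fields, function(f) f$kind, character(1))
  if (!all(kinds == "interframe"))
    coce_stop("cumulate() requires interframe fields; got kind '%s'",
              kinds[kinds != "interframe"][1])
  dims <- vapply(fields, function(f) dim(f$values), integer(2))
  if (any(dims != dims[, 1]))
    coce_stop("strain fields have mismatched shapes")
  f1 <- fields[[1]]
  acc <- matrix(0, nrow(f1$values), ncol(f1$values))
  mask <- matrix(TRUE, nrow(f1$values), ncol(f1$values))
  out <- vector("list", length(fields))
  for (k in seq_along(fields)) {
    fk <- fields[[k]]
    mask <- mask & fk$valid_mask
    v <- fk$values
    v[!fk$valid_mask] <- 0  # masked anyway; keep the sum finite
    acc <- acc + v
    out[[k]] <- new_strain_field(acc, mask, f1$window_axial_um,
                                 f1$window_lateral_um, f1$axial_lag_px,
                                 "cumulative", meta = f1$meta)
  }
  out
}

#' Full strain-estimation pass over a frame series
#'
#' Convenience wrapper: applies [interframe_field()] and [vector_strain()]
#' to every consecutive frame pair and returns both the interframe fields
#' and their [cumulate()]d sums.
#'
#' @param series A `"coce_series"`.
#' @inheritParams vector_strain
#' @return List with `interframe` and `cumulative` lists of strain fields.
#' @export
estimate_strains <- function(series, window_axial_um = 100,
                             window_lateral_um = 100, axial_lag_px = 3L,
                             amp_floor = 0.25) {
  stopifnot(inherits(series, "coce_series"))
  nf <- dim(series$data)[1]
  if (nf < 2) coce_stop("a series needs at least 2 frames")
  meta <- series[c("wavelength_um", "refractive_index", "axial_pixel_um",
                   "lateral_pixel_um", "silicone_px", "E_sil")]
  inc <- vector("list", nf - 1L)
  for (f in seq_len(nf - 1L)) {
    ifl <- interframe_field(series$data[f, , ], series$data[f + 1L, , ],
                            meta = meta)
    inc[[f]] <- vector_strain(ifl, window_axial_um, window_lateral_um,
                              axial_lag_px, amp_floor)
  }
  list(interframe = inc, cumulative = cumulate(inc))
}

#' @export
print.coce_strain <- function(x, ...) {
  cat(sprintf("%s strain field: %d x %d px, window %g x %g um, lag %d px; %.1f%% valid\n",
              x$kind, nrow(x$values), ncol(x$values),
              x$window_axial_um, x$window_lateral_um, x$axial_lag_px,
              100 * mean(x$valid_mask)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
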