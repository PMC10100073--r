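# Shared fixture builders. Everything is generated in code at test time.

# Small homogeneous phantom: 300 um silicone over one tissue class.
homog_phantom <- function(E0, beta = 0, depth_px = 150L, lateral_px = 48L,
                          lateral_pixel_um = 12, is_nonsignal = FALSE,
                          silicone_thickness_um = 200, E_sil = 100) {
  phantom_spec(
    depth_px = depth_px, lateral_px = lateral_px,
    lateral_pixel_um = lateral_pixel_um,
    silicone_thickness_um = silicone_thickness_um, E_sil = E_sil,
    classes = list(mechanical_class(1, "tissue", E0, beta,
                                    is_nonsignal = is_nonsignal)),
    background = 1)
}

quick_acq <- function(n_frames = 40L, max_stress_kPa = 6, snr_db = Inf,
                      seed = 1L) {
  acquisition_spec(n_frames = n_frames, max_stress_kPa = max_stress_kPa,
                   snr_db = snr_db, seed = seed)
}

# Fully developed speckle frame (complex circular Gaussian).
speckle_frame <- function(D, W, seed = 1) {
  set.seed(seed)
  matrix(complex(real = rnorm(D * W), imaginary = rnorm(D * W)) / sqrt(2),
         D, W)
}

default_meta <- function(axial_pixel_um = 4, lateral_pixel_um = 8) {
  list(wavelength_um = 1.31, refractive_index = 1.4,
       axial_pixel_um = axial_pixel_um, lateral_pixel_um = lateral_pixel_um)
}

phase_rate <- function(meta) {
  4 * pi * meta$refractive_index / meta$wavelength_um  # rad per um
}

# Frame pair with a prescribed axial strain profile (noiseless).
strained_pair <- function(eps_profile, W = 48, meta = default_meta(),
                          seed = 2) {
  D <- length(eps_profile)
  base <- speckle_frame(D, W, seed)
  u <- cumsum(eps_profile) * meta$axial_pixel_um
  list(a = base, b = base * exp(1i * phase_rate(meta) * u), meta = meta)
}

# Hand-rolled strain field object for unit tests that bypass estimation.
fake_strain <- function(values, mask = NULL, kind = "cumulative",
                        window_axial_um = 100, window_lateral_um = 100,
                        axial_lag_px = 3L, meta = default_meta()) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  structure(
    list(values = values, valid_mask = mask,
         window_axial_um = window_axial_um,
         window_lateral_um = window_lateral_um,
         axial_lag_px = axial_lag_px, kind = kind, meta = meta),
    class = "coce_strain")
}

# Brute-force strain oracle: unwrap interframe phase along depth, then a
# per-pixel least-squares slope over the same rectangular window. Only the
# requested pixels are evaluated (it is an O(window) loop per pixel).
unwrap_ls_strain <- function(frame_a, frame_b, meta, rows, cols,
                             window_axial_um = 100, window_lateral_um = 100) {
  dphi_w <- Arg(Conj(frame_a) * frame_b)
  unwrap1 <- function(p) {
    d <- diff(p)
    d <- d - 2 * pi * round(d / (2 * pi))
    cumsum(c(p[1], d))
  }
  dphi <- apply(dphi_w, 2L, unwrap1)
  K <- phase_rate(meta)
  D <- nrow(dphi); W <- ncol(dphi)
  wpx <- function(um, px) {
    n <- max(1L, round(um / px)); if (n %% 2 == 0) n <- n + 1L; n
  }
  wa <- wpx(window_axial_um, meta$axial_pixel_um)
  wl <- wpx(window_lateral_um, meta$lateral_pixel_um)
  z <- seq_len(D) * meta$axial_pixel_um
  out <- matrix(NA_real_, length(rows), length(cols))
  for (a in seq_along(rows)) {
    i <- rows[a]
    r <- max(1, i - wa %/% 2):min(D, i + wa %/% 2)
    for (b in seq_along(cols)) {
      j <- cols[b]
      cc <- max(1, j - wl %/% 2):min(W, j + wl %/% 2)
      zz <- rep(z[r], times = length(cc))
      pp <- as.vector(dphi[r, cc])
      out[a, b] <- sum((zz - mean(zz)) * (pp - mean(pp))) /
        sum((zz - mean(zz))^2) / K
    }
  }
  out
}

# Flood-fill 8-connected labelling oracle (queue-based, pure R).
flood_label <- function(mask) {
  D <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, D, W)
  nxt <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      i <- (p - 1L) %% D + 1L; j <- (p - 1L) %/% D + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= D && jj >= 1 && jj <= W) {
          q <- (jj - 1L) * D + ii
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- nxt
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

# Independent subtype decision oracle (mirrors the documented table).
subtype_oracle <- function(h520, h950, gl, loss, floor = 0.02) {
  if (!h520 && !h950) return("NON_CANCEROUS")
  if (loss >= 0.5) {
    if (h950 && !gl) return("MAC")
    return("INDETERMINATE")
  }
  if (loss > floor) {
    if (gl && !h950) return("CRAC_CRIBRIFORM")
    return("INDETERMINATE")
  }
  if (gl && !h950) return("LOW_GRADE_CRAC")
  if (h950 && !gl) return("HIGH_GRADE_CRAC")
  "INDETERMINATE"
}
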