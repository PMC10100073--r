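#' Acquisition settings for a simulated compression series
#'
#' Mirrors the instrument used for C-OCE imaging: a 1310 nm spectral-domain
#' OCT system with 15 um axial and 25 um lateral resolution, acquiring on
#' the order of one hundred B-scans while the sample is compressed by the
#' probe window up to several kPa. The per-frame stress increment must be
#' small enough that no pixel strains by more than 1% between consecutive
#' frames — the working range of the phase-gradient strain estimator.
#'
#' @param n_frames Number of B-scans acquired during compression (>= 2).
#' @param max_stress_kPa Final applied stress, kPa; must exceed the upper
#'   edge of the standardized stress window (5 kPa) for tangent-modulus
#'   mapping to succeed downstream.
#' @param wavelength_um Central wavelength, um.
#' @param psf_axial_um,psf_lateral_um Gaussian point-spread function FWHM.
#' @param snr_db Additive complex-noise level relative to mean speckle
#'   power, dB; `Inf` disables noise.
#' @param seed Integer seed; the simulation is bit-reproducible for a fixed
#'   spec and seed.
#' @return An object of class `"acquisition_spec"`.
#' @export
acquisition_spec <- function(n_frames = 100L, max_stress_kPa = 6,
                             wavelength_um = 1.31,
                             psf_axial_um = 15, psf_lateral_um = 25,
                             snr_db = 25, seed = 1L) {
  if (n_frames < 2) coce_stop("n_frames must be >= 2")
  if (max_stress_kPa < 0) coce_stop("max_stress_kPa must be >= 0")
  if (wavelength_um <= 0) coce_stop("wavelength_um must be positive")
  structure(
    list(n_frames = as.integer(n_frames), max_stress_kPa = max_stress_kPa,
         wavelength_um = wavelength_um, psf_axial_um = psf_axial_um,
         psf_lateral_um = psf_lateral_um, snr_db = snr_db,
         seed = as.integer(seed)),
    class = "acquisition_spec")
}

# Closed-form local strain under the affine tangent-modulus law:
# eps(sigma) = integral_0^sigma dE/E_t = log(1 + beta*sigma/E0)/beta,
# reducing to sigma/E0 for linear material.
strain_of_stress <- function(E0, beta, sigma) {
  out <- sigma / E0
  nz <- beta > 0
  if (any(nz)) out[nz] <- log1p(beta[nz] * sigma / E0[nz]) / beta[nz]
  out
}

#' Simulate the complex OCT frame series of a compressed phantom
#'
#' Forward model of the physics that the reconstruction inverts. Mechanics
#' is a one-dimensional series stack per lateral column: the applied stress
#' is uniform along each column, every pixel strains according to its local
#' tangent-modulus law, and axial displacement is the cumulative sum of
#' local strain from the compressed top surface. The optical signal is
#' fully developed speckle — a circular-Gaussian scatterer field scaled by
#' the local backscatter amplitude and convolved with the Gaussian PSF —
#' whose phase is advanced by \eqn{\Delta\phi(z) = (4\pi n/\lambda)\, u(z)}.
#' The speckle realization is frozen across frames (same scatterers, phase
#' advanced), so interframe decorrelation comes only from noise and strain,
#' matching the assumption of the phase-resolved method. Additive complex
#' Gaussian noise is applied at `snr_db`; non-signal pixels carry noise
#' only. Compressive strain is positive throughout the package.
#'
#' @param phantom A [build_phantom()] result (or a [phantom_spec()], which
#'   is rasterized first).
#' @param acq An [acquisition_spec()].
#' @return A list with components `series` (class `"coce_series"`: complex
#'   array `frames x depth x lateral` plus optical metadata) and `truth`
#'   (class `"coce_truth"`: per-frame stress, per-frame cumulative strain,
#'   the true tangent-modulus map at 4 kPa as a `"coce_stiffness"` object,
#'   the label map, and the ground-truth cancer area percentage).
#' @export
simulate_compression_series <- function(phantom, acq = acquisition_spec()) {
  if (inherits(phantom, "phantom_spec")) phantom <- build_phantom(phantom)
  stopifnot(inherits(phantom, "coce_phantom"), inherits(acq, "acquisition_spec"))
  sp <- phantom$spec
  D <- sp$depth_px; W <- sp$lateral_px; s <- sp$silicone_px
  nf <- acq$n_frames
  sigma <- seq(0, acq$max_stress_kPa, length.out = nf)

  # interframe strain limit: softest material bounds the per-step strain
  if (nf > 1 && acq$max_stress_kPa > 0) {
    dsig <- sigma[2] - sigma[1]
    eps_step <- max(strain_of_stress(phantom$E0, phantom$beta, dsig))
    if (eps_step > 0.01)
      coce_stop(paste0(
        "interframe strain %.2f%% exceeds the 1%% estimator limit; ",
        "raise n_frames or lower max_stress"), 100 * eps_step)
  }

  K <- 4 * pi * sp$refractive_index / acq$wavelength_um  # rad per um
  dz <- sp$axial_pixel_um
  sig_ax <- acq$psf_axial_um / (2 * sqrt(2 * log(2))) / dz
  sig_lat <- acq$psf_lateral_um / (2 * sqrt(2 * log(2))) / sp$lateral_pixel_um

  dat <- local_seed(acq$seed, {
    scat <- matrix(complex(real = stats::rnorm(D * W),
                           imaginary = stats::rnorm(D * W)) / sqrt(2),
                   D, W) * phantom$scatter_amp
    S <- gauss_blur(scat, sig_ax, sig_lat)
    sig_pow <- mean(Mod(S[phantom$scatter_amp > 0])^2)
    noise_sd <- if (is.finite(acq$snr_db))
      sqrt(sig_pow / 10^(acq$snr_db / 10) / 2) else 0

    arr <- array(complex(real = 0, imaginary = 0), dim = c(nf, D, W))
    cum_strain <- array(0, dim = c(nf, D, W))
    for (f in seq_len(nf)) {
      eps <- strain_of_stress(phantom$E0, phantom$beta, sigma[f])
      cum_strain[f, , ] <- eps
      u <- apply(eps, 2L, cumsum) * dz
      fr <- S * exp(1i * K * u)
      if (noise_sd > 0)
        fr <- fr + matrix(complex(real = stats::rnorm(D * W, sd = noise_sd),
                                  imaginary = stats::rnorm(D * W, sd = noise_sd)),
                          D, W)
      arr[f, , ] <- fr
    }
    list(arr = arr, cum_strain = cum_strain)
  })

  series <- structure(
    list(data = dat$arr,
         wavelength_um = acq$wavelength_um,
         refractive_index = sp$refractive_index,
         axial_pixel_um = dz, lateral_pixel_um = sp$lateral_pixel_um,
         silicone_px = s, E_sil = sp$E_sil,
         psf_axial_um = acq$psf_axial_um, psf_lateral_um = acq$psf_lateral_um,
         snr_db = acq$snr_db, seed = acq$seed),
    class = "coce_series")

  E4 <- phantom$E0 + 4 * phantom$beta
  vals <- E4
  vals[seq_len(s), ] <- sp$E_sil
  mask <- matrix(TRUE, D, W)
  mask[seq_len(s), ] <- FALSE
  mask[phantom$is_nonsignal] <- FALSE
  vals[!mask] <- NA_real_
  true_map <- new_stiffness(vals, mask, dz, sp$lateral_pixel_um, s)

  tissue <- row(phantom$label_map) > s
  cancer_px <- tissue & !phantom$is_nonsignal & (E4 >= 520)
  truth <- structure(
    list(stress_per_frame = sigma,
         true_cumulative_strain = dat$cum_strain,
         true_stiffness_map = true_map,
         label_map = phantom$label_map,
         cancer_area_percent = 100 * sum(cancer_px) / sum(tissue)),
    class = "coce_truth")

  list(series = series, truth = truth)
}

#' @export
print.coce_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("C-OCE complex frame series: %d frames x %d depth x %d lateral px\n",
              d[1], d[2], d[3]))
  cat(sprintf("  lambda = %g um, n = %g, pixel %g x %g um, silicone %d rows\n",
              x$wavelength_um, x$refractive_index,
              x$axial_pixel_um, x$lateral_pixel_um, x$silicone_px))
  invisible(x)
}
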