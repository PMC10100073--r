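# Synthetic cumulative strain stack for a two-layer (silicone over tissue)
# column model under a linear stress schedule.
two_layer_cum <- function(E_sil, E_tissue, sil_px, D, W, n_pairs,
                          max_stress = 6, beta = 0) {
  sig <- seq(0, max_stress, length.out = n_pairs + 1)
  lapply(seq_len(n_pairs), function(f) {
    s <- sig[f + 1]
    eps_t <- if (beta > 0) log1p(beta * s / E_tissue) / beta else s / E_tissue
    v <- rbind(matrix(s / E_sil, sil_px, W),
               matrix(eps_t, D - sil_px, W))
    fake_strain(v, kind = "cumulative",
                meta = c(default_meta(),
                         list(silicone_px = sil_px, E_sil = E_sil)))
  })
}

test_that("silicone stress follows Hooke's law on the reference layer", {
  cum <- two_layer_cum(100, 520, sil_px = 60, D = 160, W = 12, n_pairs = 10)
  # zero strain -> zero stress
  zero <- lapply(cum, function(f) { f$values[] <- 0; f })
  sig0 <- silicone_stress(zero, 60, 100, margin_px = 16)
  expect_true(all(sig0 == 0))
  # 4% silicone strain at E_sil = 100 kPa -> 4 kPa
  four <- cum[[1]]; four$values[] <- 0.04
  sig4 <- silicone_stress(list(four), 60, 100, margin_px = 16)
  expect_equal(unique(as.vector(sig4[2, ])), 4)
  expect_error(silicone_stress(cum, 5, 100, margin_px = 16), "too thin")
})

test_that("recovered stress schedule matches the simulator's ground truth", {
  ph <- homog_phantom(300, depth_px = 150, lateral_px = 32)
  sim <- simulate_compression_series(ph, quick_acq(n_frames = 20,
                                                   snr_db = 25, seed = 3))
  st <- estimate_strains(sim$series)
  sig <- silicone_stress(st$cumulative, sim$series$silicone_px,
                         sim$series$E_sil)
  rec <- rowMeans(sig)
  expect_lt(max(abs(rec - sim$truth$stress_per_frame)) /
              max(sim$truth$stress_per_frame), 0.05)
})

test_that("stress-strain records are linear for linear tissue and stiffen otherwise", {
  cum_lin <- two_layer_cum(100, 400, 60, 160, 8, 12)
  sig <- silicone_stress(cum_lin, 60, 100, margin_px = 16)
  grid <- build_stress_strain(cum_lin, sig)
  eps_px <- grid$eps[, 120, 4]
  sig_px <- grid$sigma[, 4]
  expect_equal(eps_px, sig_px / 400, tolerance = 1e-12)

  beta <- 40
  cum_nl <- two_layer_cum(100, 400, 60, 160, 8, 12, beta = beta)
  sig <- silicone_stress(cum_nl, 60, 100, margin_px = 16)
  grid <- build_stress_strain(cum_nl, sig)
  eps_px <- grid$eps[, 120, 4]
  expect_equal(eps_px, log1p(beta * grid$sigma[, 4] / 400) / beta,
               tolerance = 1e-12)
  slopes <- diff(eps_px) / diff(grid$sigma[, 4])
  expect_true(all(diff(slopes) < 0))  # tangent modulus grows with stress
})

test_that("non-monotone stress schedules are rejected", {
  cum <- two_layer_cum(100, 400, 60, 160, 8, 6)
  sig <- silicone_stress(cum, 60, 100, margin_px = 16)
  sig[4, ] <- sig[5, ] + 1  # 1 kPa drop
  expect_error(build_stress_strain(cum, sig), "tracking failed")
})

test_that("tangent modulus equals E_sil when tissue is silicone", {
  cum <- two_layer_cum(100, 100, 60, 160, 8, 12)
  sig <- silicone_stress(cum, 60, 100, margin_px = 16)
  map <- tangent_modulus_map(build_stress_strain(cum, sig))
  expect_equal(unique(round(as.vector(map$values), 9)), 100)
})

test_that("tangent modulus demands the full 3-5 kPa stress window", {
  cum <- two_layer_cum(100, 400, 60, 160, 8, 8, max_stress = 4)
  sig <- silicone_stress(cum, 60, 100, margin_px = 16)
  expect_error(tangent_modulus_map(build_stress_strain(cum, sig)),
               "insufficient compression")
})

test_that("noiseless pipeline recovers class-mean moduli within 5%", {
  for (E in c(58, 295, 724, 954)) {
    sim <- simulate_compression_series(
      homog_phantom(E, depth_px = 150, lateral_px = 32),
      quick_acq(n_frames = 40, seed = 2))
    m <- tissue_mean_stiffness(coce_fit(sim$series))
    expect_lt(abs(m / E - 1), 0.05)
  }
})

test_that("stiffening tissue reports E0 + 4 beta at the standardized stress", {
  sim <- simulate_compression_series(
    homog_phantom(500, beta = 30, depth_px = 150, lateral_px = 32),
    quick_acq(n_frames = 40, seed = 2))
  m <- tissue_mean_stiffness(coce_fit(sim$series))
  expect_lt(abs(m / (500 + 4 * 30) - 1), 0.10)
})

test_that("recovered stiffness is monotone in the true modulus", {
  means <- vapply(seq(50, 1400, by = 150), function(E) {
    sim <- simulate_compression_series(
      homog_phantom(E, depth_px = 120, lateral_px = 24),
      quick_acq(n_frames = 40, seed = 4))
    tissue_mean_stiffness(coce_fit(sim$series))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("non-signal phantom regions are masked in the stiffness map", {
  spec <- phantom_spec(
    depth_px = 180, lateral_px = 64, lateral_pixel_um = 12,
    silicone_thickness_um = 200,
    classes = list(mechanical_class(1, "stroma", 295),
                   mechanical_class(2, "mucin", 30, is_nonsignal = TRUE)),
    background = 1,
    shapes = list(shape_ellipse(380, 280, 220, 160, 2)))
  ph <- build_phantom(spec)
  sim <- simulate_compression_series(ph, quick_acq(n_frames = 40,
                                                   snr_db = 25, seed = 8))
  fit <- coce_fit(sim$series)
  # core of the mucin pocket, away from the PSF/window-blurred rim
  idx <- which(ph$is_nonsignal, arr.ind = TRUE)
  zc <- mean(range(idx[, 1])); xc <- mean(range(idx[, 2]))
  core <- idx[abs(idx[, 1] - zc) < 0.5 * diff(range(idx[, 1])) / 2 &
              abs(idx[, 2] - xc) < 0.5 * diff(range(idx[, 2])) / 2, ]
  expect_gt(mean(!fit$stiffness$signal_mask[core]), 0.95)
})

test_that("implausibly stiff pixels are clamped out of the signal mask", {
  cum <- two_layer_cum(100, 100000, 60, 160, 8, 12)
  sig <- silicone_stress(cum, 60, 100, margin_px = 16)
  map <- tangent_modulus_map(build_stress_strain(cum, sig))
  tissue_rows <- 61:160
  expect_true(all(!map$signal_mask[tissue_rows, ]))
})

test_that("silicone auto-detection finds the layer boundary", {
  sim <- simulate_compression_series(
    homog_phantom(500, depth_px = 150, lateral_px = 32),
    quick_acq(n_frames = 20, seed = 5))
  st <- estimate_strains(sim$series)
  est <- detect_silicone(st$cumulative)
  true_px <- sim$series$silicone_px
  # within half an averaging window of the true interface
  expect_lt(abs(est - true_px), 15)
})
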