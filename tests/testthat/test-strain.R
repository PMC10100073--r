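test_that("interframe field argument reflects the phase shift", {
  a <- speckle_frame(60, 20)
  expect_equal(max(abs(Arg(interframe_field(a, a)$field))), 0)
  shifted <- interframe_field(a, a * exp(1i * 0.3))
  expect_equal(unique(as.vector(round(Arg(shifted$field), 12))), 0.3)
  expect_error(interframe_field(a, a[, 1:10]), "shapes differ")
})

test_that("vector strain recovers uniform noiseless strain ramps", {
  # zero deformation
  p0 <- strained_pair(rep(0, 150))
  sf0 <- vector_strain(interframe_field(p0$a, p0$b, p0$meta))
  expect_true(all(abs(sf0$values[sf0$valid_mask]) < 1e-12))

  # 0.5% uniform ramp recovered within 1e-4, 1% within the working range
  for (eps in c(0.005, 0.01)) {
    p <- strained_pair(rep(eps, 150))
    sf <- vector_strain(interframe_field(p$a, p$b, p$meta))
    expect_lt(max(abs(sf$values[sf$valid_mask] - eps)), 1e-4)
  }
})

test_that("strains up to 1% survive raw phase wrapping across pi", {
  # deep image: total interframe phase spans many multiples of pi
  p <- strained_pair(rep(0.01, 400))
  total_phase <- phase_rate(p$meta) * sum(rep(0.01, 400)) * p$meta$axial_pixel_um
  expect_gt(total_phase, 2 * pi)  # wrapping definitely occurs
  sf <- vector_strain(interframe_field(p$a, p$b, p$meta))
  vals <- sf$values[sf$valid_mask]
  expect_true(all(vals > 0))
  expect_lt(max(abs(vals / 0.01 - 1)), 0.001)
})

test_that("recovered strain is linear in the true displacement", {
  base_eps <- rep(0.008, 150)
  p1 <- strained_pair(base_eps)
  p2 <- strained_pair(0.3 * base_eps)
  s1 <- vector_strain(interframe_field(p1$a, p1$b, p1$meta))
  s2 <- vector_strain(interframe_field(p2$a, p2$b, p2$meta))
  ratio <- s2$values[s2$valid_mask] / s1$values[s1$valid_mask]
  expect_lt(max(abs(ratio - 0.3)), 1e-6)
})

test_that("vector strain agrees with the unwrap + least-squares oracle", {
  # piecewise two-layer strain profile, noiseless speckle
  eps <- c(rep(0.002, 100), rep(0.009, 100))
  p <- strained_pair(eps, W = 40)
  sf <- vector_strain(interframe_field(p$a, p$b, p$meta))
  rows <- c(30, 50, 70, 150, 170)
  cols <- c(10, 20, 30)
  oracle <- unwrap_ls_strain(p$a, p$b, p$meta, rows, cols)
  got <- sf$values[rows, cols]
  expect_lt(max(abs(got / oracle - 1)), 0.02)
})

test_that("a sharp strain step is resolved within half the window", {
  eps1 <- 0.002; eps2 <- 0.008
  p <- strained_pair(c(rep(eps1, 100), rep(eps2, 100)), W = 48)
  sf <- vector_strain(interframe_field(p$a, p$b, p$meta),
                      window_axial_um = 100)
  prof <- rowMeans(sf$values, na.rm = TRUE)
  z <- seq_along(prof) * p$meta$axial_pixel_um
  lo <- eps1 + 0.25 * (eps2 - eps1)
  hi <- eps1 + 0.75 * (eps2 - eps1)
  sel <- 60:140
  width <- stats::approx(prof[sel], z[sel], xout = hi, ties = "ordered")$y -
    stats::approx(prof[sel], z[sel], xout = lo, ties = "ordered")$y
  expect_lte(width, 50)
})

test_that("oversized windows and bad lags are rejected", {
  p <- strained_pair(rep(0.005, 50), W = 10)
  ifl <- interframe_field(p$a, p$b, p$meta)
  expect_error(vector_strain(ifl, window_axial_um = 10000), "larger than")
  expect_error(vector_strain(ifl, axial_lag_px = 0), "axial_lag_px")
})

test_that("cumulate sums increments and intersects validity masks", {
  v <- matrix(0.001, 30, 10)
  fields <- replicate(10, fake_strain(v, kind = "interframe"),
                      simplify = FALSE)
  cum <- cumulate(fields)
  expect_length(cum, 10)
  expect_equal(unique(as.vector(cum[[10]]$values)), 0.01)
  expect_equal(cum[[10]]$kind, "cumulative")

  # a pixel invalid in one increment is invalid in every later sum
  m <- matrix(TRUE, 30, 10); m[5, 5] <- FALSE
  fields[[3]] <- fake_strain(v, mask = m, kind = "interframe")
  cum <- cumulate(fields)
  expect_true(cum[[2]]$valid_mask[5, 5])
  expect_false(cum[[3]]$valid_mask[5, 5])
  expect_false(cum[[10]]$valid_mask[5, 5])

  expect_error(cumulate(list(fake_strain(v, kind = "cumulative"))),
               "interframe")
})

test_that("non-signal pixels fall below the vector-sum validity floor", {
  # left half carries speckle signal, right half is pure noise that is
  # redrawn between the two frames (incoherent)
  D <- 120; W <- 40
  amp <- cbind(matrix(1, D, W / 2), matrix(0, D, W / 2))
  sig <- speckle_frame(D, W, seed = 6) * amp
  set.seed(7)
  noise <- function() matrix(complex(real = rnorm(D * W, sd = 0.1),
                                     imaginary = rnorm(D * W, sd = 0.1)),
                             D, W)
  sf <- vector_strain(interframe_field(sig + noise(), sig + noise(),
                                       default_meta()))
  rows <- 20:(D - 20)
  # columns clear of the half-window overlap with the signal half
  expect_lt(mean(sf$valid_mask[rows, (W / 2 + 7):(W - 6)]), 0.05)
  expect_gt(mean(sf$valid_mask[rows, 6:(W / 2 - 6)]), 0.95)
})
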