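# Internal numeric helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All randomness in the package flows through this; no global state leaks.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated sliding-window sums over a matrix: out[i, j] is the sum of M over
# the (h x w) window centred at (i, j), clipped at the image borders.
# h and w must be odd. Implemented with cumulative sums (integral image).
box_sum <- function(M, h, w) {
  stopifnot(h %% 2L == 1L, w %% 2L == 1L)
  D <- nrow(M); W <- ncol(M)
  h2 <- h %/% 2L; w2 <- w %/% 2L
  cs <- rbind(0, apply(M, 2L, cumsum))
  r1 <- pmax(seq_len(D) - h2, 1L)
  r2 <- pmin(seq_len(D) + h2, D)
  rows <- cs[r2 + 1L, , drop = FALSE] - cs[r1, , drop = FALSE]
  cs2 <- cbind(0, t(apply(rows, 1L, cumsum)))
  c1 <- pmax(seq_len(W) - w2, 1L)
  c2 <- pmin(seq_len(W) + w2, W)
  cs2[, c2 + 1L, drop = FALSE] - cs2[, c1, drop = FALSE]
}

# Number of in-image pixels contributing to each truncated window.
box_count <- function(D, W, h, w) {
  box_sum(matrix(1, D, W), h, w)
}

# Convert a physical window size to an odd pixel count (>= 1).
window_px <- function(size_um, pixel_um) {
  n <- max(1L, as.integer(round(size_um / pixel_um)))
  if (n %% 2L == 0L) n <- n + 1L
  n
}

# Dense banded Gaussian convolution matrix (truncated at 4 sigma, rescaled so
# rows sum to 1 in the interior). Used for separable PSF blur.
gauss_band <- function(n, sigma_px) {
  if (sigma_px <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) {
    d <- abs(i - j)
    ifelse(d <= 4 * sigma_px, exp(-d^2 / (2 * sigma_px^2)), 0)
  })
  K / sum(exp(-(seq(-ceiling(4 * sigma_px), ceiling(4 * sigma_px)))^2 /
                (2 * sigma_px^2)))
}

# Separable Gaussian blur of a (possibly complex) matrix.
gauss_blur <- function(M, sigma_axial_px, sigma_lateral_px) {
  Ka <- gauss_band(nrow(M), sigma_axial_px)
  Kl <- gauss_band(ncol(M), sigma_lateral_px)
  Ka %*% M %*% Kl
}

# Consistent error helper: all user-facing errors carry the package prefix.
coce_stop <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
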