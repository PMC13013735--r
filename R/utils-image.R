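# Internal image primitives: separable correlation, bilinear sampling,
# pyramid resampling. Frames are plain numeric matrices with rows = y
# (top-down) and columns = x; the package-wide coordinate convention is
# (x, y) = (column, row), origin top-left, 0-based, pixel centers at
# integer coordinates.

#' Sampled, normalized 1-D Gaussian kernel
#' @noRd
gaussian_kernel1d <- function(sigma, radius = ceiling(3 * sigma)) {
  d <- seq.int(-radius, radius)
  k <- exp(-d^2 / (2 * sigma^2))
  list(w = k / sum(k), d = d)
}

# Correlate along x (columns) with replicate boundary:
# out[, j] = sum_i w[i] * X[, clamp(j + d[i])]
corr_x <- function(X, w, d) corr_x_cpp(X, w, as.integer(d))

# Correlate along y (rows), replicate boundary.
corr_y <- function(X, w, d) corr_y_cpp(X, w, as.integer(d))

#' Separable correlation with kernels along x then y
#' @noRd
sep_corr <- function(X, kx, ky) {
  corr_y(corr_x(X, kx$w, kx$d), ky$w, ky$d)
}

#' Gaussian blur (separable, replicate boundary)
#' @noRd
gauss_blur <- function(X, sigma) {
  k <- gaussian_kernel1d(sigma)
  sep_corr(X, k, k)
}

#' Bilinear sampling at fractional (x, y) positions, 0-based coordinates.
#' Positions are clamped to the frame; returns a vector aligned with xs.
#' @noRd
bilinear_sample <- function(F, xs, ys) bilinear_cpp(F, xs, ys)

#' Halve resolution: Gaussian pre-blur then decimate odd pixels
#' @noRd
pyr_down <- function(X) {
  B <- gauss_blur(X, 1)
  B[seq.int(1L, nrow(X), 2L), seq.int(1L, ncol(X), 2L), drop = FALSE]
}

#' Bilinear resize to (nr, nc); values are interpolated, not rescaled
#' @noRd
resize_bilinear <- function(F, nr, nc) {
  sx <- ncol(F) / nc
  sy <- nrow(F) / nr
  xs <- (seq_len(nc) - 0.5) * sx - 0.5
  ys <- (seq_len(nr) - 0.5) * sy - 0.5
  grid_x <- rep(xs, each = nr)
  grid_y <- rep(ys, times = nc)
  matrix(bilinear_sample(F, grid_x, grid_y), nr, nc)
}
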