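# Dense optical flow by local polynomial expansion, plus grid
# downsampling and magnitude thresholding of the resulting field.

#' Default dense-flow parameters
#'
#' Canonical defaults for the polynomial-expansion pyramid estimator:
#' 3 pyramid levels at scale 0.5, a 15-pixel Gaussian integration window,
#' 3 refinement iterations per level, polynomial neighborhood 5 with
#' applicability sigma 1.2.
#'
#' @param levels Number of pyramid scales, including full resolution.
#' @param winsize Integration window diameter in pixels (odd).
#' @param iterations Displacement refinement iterations per level.
#' @param poly_n Polynomial expansion neighborhood diameter (odd).
#' @param poly_sigma Gaussian applicability sigma for the expansion.
#' @return A named list of flow parameters.
#' @export
flow_params <- function(levels = 3, winsize = 15, iterations = 3,
                        poly_n = 5, poly_sigma = 1.2) {
  stopifnot(levels >= 1, winsize >= 3, iterations >= 1,
            poly_n >= 3, poly_n %% 2 == 1, poly_sigma > 0)
  list(levels = as.integer(levels), winsize = as.integer(winsize),
       iterations = as.integer(iterations), poly_n = as.integer(poly_n),
       poly_sigma = poly_sigma)
}

# Quadratic polynomial expansion of one frame:
# f(x + d) ~ d' A d + b' d + c around every pixel, with a Gaussian
# applicability of radius (poly_n - 1)/2. Returns the per-pixel
# coefficient fields A11, A12, A22, bx, by.
poly_expand <- function(f, poly_n = 5, poly_sigma = 1.2) {
  r <- (poly_n - 1L) %/% 2L
  g <- gaussian_kernel1d(poly_sigma, r)
  d <- g$d
  k0 <- list(w = g$w,       d = d)
  k1 <- list(w = g$w * d,   d = d)
  k2 <- list(w = g$w * d^2, d = d)

  # row passes along x, then column passes along y
  X0 <- corr_x(f, k0$w, d); X1 <- corr_x(f, k1$w, d); X2 <- corr_x(f, k2$w, d)
  m00 <- corr_y(X0, k0$w, d)
  m01 <- corr_y(X0, k1$w, d)
  m02 <- corr_y(X0, k2$w, d)
  m10 <- corr_y(X1, k0$w, d)
  m11 <- corr_y(X1, k1$w, d)
  m20 <- corr_y(X2, k0$w, d)

  # metric G = sum w(dx) w(dy) basis basis' for basis (1, x, y, x2, y2, xy);
  # with a symmetric separable weight only (1, x2, y2) couple.
  s2 <- sum(g$w * d^2)
  s4 <- sum(g$w * d^4)
  G3 <- matrix(c(1,  s2,    s2,
                 s2, s4,    s2^2,
                 s2, s2^2,  s4), 3, 3, byrow = TRUE)
  Gi <- solve(G3)

  list(
    bx  = m10 / s2,
    by  = m01 / s2,
    A11 = Gi[2, 1] * m00 + Gi[2, 2] * m20 + Gi[2, 3] * m02,
    A22 = Gi[3, 1] * m00 + Gi[3, 2] * m20 + Gi[3, 3] * m02,
    A12 = m11 / s2^2 / 2
  )
}

# One pyramid level of displacement refinement. u0, v0 hold the current
# displacement estimate at this level's resolution.
refine_flow_level <- function(pe1, pe2, u0, v0, winsize, iterations) {
  nr <- nrow(u0); nc <- ncol(u0)
  wr <- (winsize - 1L) %/% 2L
  wk <- gaussian_kernel1d((winsize - 1) / 4, wr)
  xs0 <- rep(seq_len(nc) - 1, each = nr)
  ys0 <- rep(seq_len(nr) - 1, times = nc)

  for (it in seq_len(iterations)) {
    xw <- xs0 + as.vector(u0)
    yw <- ys0 + as.vector(v0)
    A11w <- matrix(bilinear_sample(pe2$A11, xw, yw), nr, nc)
    A12w <- matrix(bilinear_sample(pe2$A12, xw, yw), nr, nc)
    A22w <- matrix(bilinear_sample(pe2$A22, xw, yw), nr, nc)
    bxw  <- matrix(bilinear_sample(pe2$bx,  xw, yw), nr, nc)
    byw  <- matrix(bilinear_sample(pe2$by,  xw, yw), nr, nc)

    A11 <- (pe1$A11 + A11w) / 2
    A12 <- (pe1$A12 + A12w) / 2
    A22 <- (pe1$A22 + A22w) / 2
    dbx <- -0.5 * (bxw - pe1$bx) + A11 * u0 + A12 * v0
    dby <- -0.5 * (byw - pe1$by) + A12 * u0 + A22 * v0

    G11 <- sep_corr(A11 * A11 + A12 * A12, wk, wk)
    G12 <- sep_corr(A12 * (A11 + A22),     wk, wk)
    G22 <- sep_corr(A12 * A12 + A22 * A22, wk, wk)
    h1  <- sep_corr(A11 * dbx + A12 * dby, wk, wk)
    h2  <- sep_corr(A12 * dbx + A22 * dby, wk, wk)

    # Tikhonov damping scaled to the field so textureless regions give
    # zero displacement instead of dividing by a vanishing determinant.
    lam <- 1e-12 + 1e-4 * mean(G11 + G22)
    G11 <- G11 + lam
    G22 <- G22 + lam
    det <- G11 * G22 - G12 * G12
    u0 <- (G22 * h1 - G12 * h2) / det
    v0 <- (G11 * h2 - G12 * h1) / det
  }
  list(u = u0, v = v0)
}

#' Estimate dense optical flow between two frames
#'
#' Per-pixel displacement from `frame_a` to `frame_b` by the
#' polynomial-expansion method: each local neighborhood is approximated by
#' a quadratic polynomial and the displacement is recovered from the change
#' in coefficients, coarse-to-fine over a multi-resolution pyramid.
#' Positive `u` is rightward motion (increasing x), positive `v` downward
#' (increasing y), in pixels per frame interval.
#'
#' @param frame_a,frame_b Numeric intensity matrices of identical shape
#'   (rows = y, columns = x).
#' @param params Parameter list from [flow_params()].
#' @return A `FlowField`: list with matrices `u`, `v` the shape of the input.
#' @examples
#' f <- matrix(runif(64 * 64), 64, 64)
#' fl <- estimate_dense_flow(f, f)
#' max(abs(fl$u))  # ~0: no motion between identical frames
#' @export
estimate_dense_flow <- function(frame_a, frame_b, params = flow_params()) {
  if (!is.matrix(frame_a) || !is.matrix(frame_b))
    stop("frames must be numeric matrices")
  if (!all(dim(frame_a) == dim(frame_b)))
    stop("frame shape mismatch: ", paste(dim(frame_a), collapse = "x"),
         " vs ", paste(dim(frame_b), collapse = "x"))
  flow_between(flow_pyramid(frame_a, params), flow_pyramid(frame_b, params),
               params)
}

# Multi-resolution pyramid of polynomial expansions for one frame.
# Precomputing this per frame lets consecutive flow computations share it.
flow_pyramid <- function(frame, params = flow_params()) {
  levels <- list()
  f <- frame
  lv <- 1L
  repeat {
    levels[[lv]] <- list(
      dim = dim(f),
      pe = poly_expand(f, params$poly_n, params$poly_sigma)
    )
    if (lv >= params$levels || min(dim(f)) < 2L * params$winsize) break
    f <- pyr_down(f)
    lv <- lv + 1L
  }
  levels
}

# Coarse-to-fine displacement estimation between two expansion pyramids.
flow_between <- function(pyr_a, pyr_b, params = flow_params()) {
  lv <- min(length(pyr_a), length(pyr_b))
  u <- NULL; v <- NULL
  for (level in rev(seq_len(lv))) {
    d <- pyr_a[[level]]$dim
    if (is.null(u)) {
      u <- matrix(0, d[1], d[2])
      v <- matrix(0, d[1], d[2])
    } else {
      u <- resize_bilinear(u, d[1], d[2]) * 2
      v <- resize_bilinear(v, d[1], d[2]) * 2
    }
    fl <- refine_flow_level(pyr_a[[level]]$pe, pyr_b[[level]]$pe, u, v,
                            params$winsize, params$iterations)
    u <- fl$u; v <- fl$v
  }
  structure(list(u = u, v = v), class = "FlowField")
}

#' Downsample a dense flow field onto a uniform grid
#'
#' Divides the frame into square cells of `cell_size` pixels and averages
#' the per-pixel displacement vectors within each cell. Edge cells not
#' fully covered by the frame average over the pixels actually present.
#'
#' @param flow A `FlowField` from [estimate_dense_flow()].
#' @param cell_size Cell edge length in pixels (>= 1).
#' @return A `GridFlowField`: list with `cell_u`, `cell_v`, `cell_speed`
#'   (ny x nx matrices), cell center coordinates `centers_x`, `centers_y`
#'   (pixel units, 0-based), `cell_size`, and the source frame size.
#' @export
downsample_flow <- function(flow, cell_size) {
  stopifnot(inherits(flow, "FlowField"), cell_size >= 1)
  cell_size <- as.integer(cell_size)
  nr <- nrow(flow$u); nc <- ncol(flow$u)
  if (cell_size > max(nr, nc))
    warning("cell_size exceeds frame size; using a single cell")

  iy <- (seq_len(nr) - 1L) %/% cell_size   # cell row per pixel row
  ix <- (seq_len(nc) - 1L) %/% cell_size
  ny <- max(iy) + 1L; nx <- max(ix) + 1L
  # group id per pixel, column-major over (cell row, cell col)
  grp <- rep(iy, times = nc) + ny * rep(ix, each = nr)

  cnt <- rowsum(rep(1, nr * nc), grp)
  su  <- rowsum(as.vector(flow$u), grp)
  sv  <- rowsum(as.vector(flow$v), grp)
  cu  <- matrix(su / cnt, ny, nx)
  cv  <- matrix(sv / cnt, ny, nx)

  centers_x <- vapply(seq_len(nx) - 1L,
                      function(i) mean((seq_len(nc) - 1)[ix == i]), 0)
  centers_y <- vapply(seq_len(ny) - 1L,
                      function(i) mean((seq_len(nr) - 1)[iy == i]), 0)

  structure(list(cell_size = cell_size, nx = nx, ny = ny,
                 centers_x = centers_x, centers_y = centers_y,
                 cell_u = cu, cell_v = cv,
                 cell_speed = sqrt(cu^2 + cv^2),
                 width = nc, height = nr),
            class = "GridFlowField")
}

#' Zero out sub-threshold grid motion
#'
#' Cells whose speed magnitude is below `cutoff` have both velocity
#' components replaced with exactly zero, leaving a sparse field of
#' significant motion vectors. Idempotent.
#'
#' @param grid A `GridFlowField`.
#' @param cutoff Minimum speed to keep, px per frame interval (>= 0).
#' @return The thresholded `GridFlowField`.
#' @export
threshold_flow <- function(grid, cutoff) {
  stopifnot(inherits(grid, "GridFlowField"))
  if (cutoff < 0) stop("cutoff must be non-negative")
  kill <- grid$cell_speed < cutoff
  grid$cell_u[kill] <- 0
  grid$cell_v[kill] <- 0
  grid$cell_speed <- sqrt(grid$cell_u^2 + grid$cell_v^2)
  grid
}

#' Extract nonzero grid cells as motion points
#'
#' Returns the positions and velocities of all cells that survived
#' thresholding, in row-major grid order (top row first, left to right) so
#' downstream clustering is reproducible.
#'
#' @param grid A thresholded `GridFlowField`.
#' @return A data frame with columns `x`, `y` (cell centers, px), `u`, `v`,
#'   `speed`; zero rows if nothing moves.
#' @export
motion_points <- function(grid) {
  stopifnot(inherits(grid, "GridFlowField"))
  idx <- which(grid$cell_speed > 0, arr.ind = TRUE)
  df <- data.frame(
    x = grid$centers_x[idx[, 2]],
    y = grid$centers_y[idx[, 1]],
    u = grid$cell_u[idx],
    v = grid$cell_v[idx],
    speed = grid$cell_speed[idx]
  )
  df[order(df$y, df$x), , drop = FALSE]
}
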