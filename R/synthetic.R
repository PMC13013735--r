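# Ground-truthed synthetic scenes emulating field footage of a waving
# lek: many small, near-stationary bodies on a static low-contrast
# textured background, each producing brief periodic local motion with a
# small bright claw patch.
#
# Claw kinematics: every male waves the same-side claw, held on an arm
# above the body; the patch orbits the arm pivot (offset upward from the
# body center) at radius claw_size/2 with a nonuniform angular speed,
# alpha(t) = psi - beta*sin(psi), psi = 2*pi*t/T + offset, so claw speed
# has exactly one maximum per wave cycle (at psi = pi mod 2*pi) — a fast
# flick and a slow recovery. Those maxima are the planted wave peaks,
# phase zero by the package-wide convention. duty_cycle < 1 freezes the
# claw outside a window centered on the flick, creating inactive periods
# within each cycle. The orbit clears the body so the static scene under
# the moving patch is uniform and the measured speed peak is unbiased.

#' Synthetic scene configuration
#'
#' @param width,height Frame size, px.
#' @param n_frames Number of frames (>= 2).
#' @param frame_rate Frames per second.
#' @param n_wavers Number of waving individuals (0 allowed).
#' @param body_radius Body blob radius, px.
#' @param claw_size Claw displacement amplitude and apparent patch size,
#'   px (~15 matches low-resolution field footage).
#' @param wave_period_s Wave period per individual, seconds; scalar or
#'   length-`n_wavers` vector.
#' @param wave_phase_offset Phase offsets in radians; `NULL` draws them
#'   from a wrapped normal (sd 1.18 rad) around a random common phase,
#'   emulating a partially synchronized lek (group order parameter ~0.5,
#'   comparable to field observations); pass explicit offsets for other
#'   regimes.
#' @param duty_cycle Fraction of each cycle with claw motion, in (0, 1].
#' @param min_separation Minimum distance between body centers, px.
#' @param noise_sigma Per-pixel Gaussian noise sd, intensity units
#'   (frames live in \[0, 1\]).
#' @param metric_scale Optional meters per pixel recorded in the output.
#' @param seed Integer seed fixing placement, offsets, texture and noise.
#' @return A `SceneConfig` list.
#' @export
scene_config <- function(width = 480, height = 360, n_frames = 600,
                         frame_rate = 30, n_wavers = 10, body_radius = 6,
                         claw_size = 15, wave_period_s = 2.0,
                         wave_phase_offset = NULL, duty_cycle = 1.0,
                         min_separation = 70, noise_sigma = 0.005,
                         metric_scale = NULL, seed = 1) {
  stopifnot(width >= 32, height >= 32, n_frames >= 2, frame_rate > 0,
            n_wavers >= 0, body_radius > 0, claw_size > 0,
            all(wave_period_s > 0), duty_cycle > 0, duty_cycle <= 1,
            min_separation > 0, noise_sigma >= 0)
  if (length(wave_period_s) == 1) wave_period_s <- rep(wave_period_s, n_wavers)
  if (n_wavers > 0 && length(wave_period_s) != n_wavers)
    stop("wave_period_s must be scalar or length n_wavers")
  if (!is.null(wave_phase_offset) && length(wave_phase_offset) != n_wavers)
    stop("wave_phase_offset must be length n_wavers")
  structure(list(width = width, height = height, n_frames = n_frames,
                 frame_rate = frame_rate, n_wavers = n_wavers,
                 body_radius = body_radius, claw_size = claw_size,
                 wave_period_s = wave_period_s,
                 wave_phase_offset = wave_phase_offset,
                 duty_cycle = duty_cycle, min_separation = min_separation,
                 noise_sigma = noise_sigma, metric_scale = metric_scale,
                 seed = seed),
            class = "SceneConfig")
}

# jittered-grid placement: guarantees pairwise >= min_separation or errors
place_wavers <- function(cfg, margin) {
  n <- cfg$n_wavers
  uw <- cfg$width - 2 * margin
  uh <- cfg$height - 2 * margin
  if (n == 0) return(matrix(0, 0, 2))
  if (uw <= 0 || uh <= 0)
    stop("infeasible packing: frame too small for waver margin")
  gc_ <- max(1L, ceiling(sqrt(n * uw / uh)))
  gr_ <- ceiling(n / gc_)
  sx <- uw / gc_; sy <- uh / gr_
  if (min(sx, sy) < cfg$min_separation)
    stop("infeasible packing: cannot place ", n, " wavers at separation ",
         cfg$min_separation, " in ", cfg$width, "x", cfg$height)
  jx <- (sx - cfg$min_separation) / 2
  jy <- (sy - cfg$min_separation) / 2
  cells <- sample(gc_ * gr_, n)   # seeded by caller
  ci <- (cells - 1) %% gc_
  ri <- (cells - 1) %/% gc_
  cbind(
    x = margin + (ci + 0.5) * sx + stats::runif(n, -jx, jx),
    y = margin + (ri + 0.5) * sy + stats::runif(n, -jy, jy)
  )
}

# claw angle at scene time t for one waver; vectorized over t.
# Returns the effective angle alpha; motion is gated to a window of width
# duty_cycle centered on the flick (psi = pi within each cycle).
claw_angle <- function(t, period, offset, duty, beta = 0.95) {
  psi <- 2 * pi * t / period + offset
  cyc <- floor(psi / (2 * pi))
  loc <- psi - 2 * pi * cyc
  lo <- pi * (1 - duty)
  hi <- pi * (1 + duty)
  eff <- 2 * pi * cyc + pmin(pmax(loc, lo), hi)
  eff - beta * sin(eff)
}

# alpha-blended Gaussian blob at fractional center (cx, cy): the blob core
# takes the blob's own intensity (img <- img + w * (value - img) with
# Gaussian weight w), so its appearance does not depend on the background
# it covers. Evaluated on a local window only.
add_blob <- function(img, cx, cy, sigma, value) {
  r <- ceiling(4 * sigma)
  xs <- max(0, floor(cx) - r):min(ncol(img) - 1, ceiling(cx) + r)
  ys <- max(0, floor(cy) - r):min(nrow(img) - 1, ceiling(cy) + r)
  w <- outer(exp(-(ys - cy)^2 / (2 * sigma^2)),
             exp(-(xs - cx)^2 / (2 * sigma^2)))
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] +
    w * (value - img[ys + 1, xs + 1])
  img
}

#' Generate a ground-truthed synthetic scene
#'
#' Renders the configured scene and returns both the frames and the
#' complete ground truth (body centers, planted wave-peak times, planted
#' phase convention). The same configuration and seed always produce
#' bit-identical frames; the caller's RNG state is left untouched.
#'
#' @param cfg A [scene_config()].
#' @return List with `frames` (a [frame_sequence()]) and `truth`, a
#'   `GroundTruth` list: `centers` (data frame `id`, `x`, `y` — the center
#'   of each waver's claw motion, plus `body_x`, `body_y`), `peaks`
#'   (data frame `id`, `peak_time_s`), `period_s`, `phase_offset`, and the
#'   generating `config`.
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "SceneConfig"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  claw_sigma <- cfg$claw_size / 4
  orbit <- cfg$claw_size / 2
  arm <- cfg$body_radius + orbit + 1   # pivot offset above the body center
  margin <- arm + orbit + ceiling(4 * claw_sigma) + 2
  centers <- place_wavers(cfg, margin)

  offsets <- cfg$wave_phase_offset %||%
    ((stats::runif(1, 0, 2 * pi) +
        stats::rnorm(cfg$n_wavers, 0, 1.18)) %% (2 * pi))

  # static background: low-contrast random texture with locally
  # normalized contrast (a homogeneous substrate, the favorable recording
  # condition), + body blobs
  tex <- gauss_blur(matrix(stats::runif(cfg$height * cfg$width),
                           cfg$height, cfg$width), 1.5)
  tex <- tex - gauss_blur(tex, 6)            # high-pass: zero-mean grain
  env <- sqrt(gauss_blur(tex^2, 6)) + 1e-8   # local contrast envelope
  tex <- tex / env
  bg <- 0.5 + 0.10 * tex / stats::sd(tex)
  for (j in seq_len(cfg$n_wavers))
    bg <- add_blob(bg, centers[j, 1], centers[j, 2],
                   cfg$body_radius / 1.5, 0.2)

  times <- (seq_len(cfg$n_frames) - 1) / cfg$frame_rate
  frames <- vector("list", cfg$n_frames)
  for (i in seq_len(cfg$n_frames)) {
    f <- bg
    for (j in seq_len(cfg$n_wavers)) {
      a <- claw_angle(times[i], cfg$wave_period_s[j], offsets[j],
                      cfg$duty_cycle)
      f <- add_blob(f, centers[j, 1] + orbit * cos(a),
                    centers[j, 2] - arm + orbit * sin(a), claw_sigma, 0.95)
    }
    if (cfg$noise_sigma > 0)
      f <- f + matrix(stats::rnorm(length(f), 0, cfg$noise_sigma),
                      nrow(f), ncol(f))
    frames[[i]] <- pmin(pmax(f, 0), 1)
  }

  duration <- (cfg$n_frames - 1) / cfg$frame_rate
  peaks <- lapply(seq_len(cfg$n_wavers), function(j) {
    # flick maxima: psi = pi (mod 2*pi)
    Tj <- cfg$wave_period_s[j]
    k <- seq.int(floor(offsets[j] / (2 * pi) - 1),
                 ceiling((2 * pi * duration / Tj + offsets[j]) / (2 * pi)) + 1)
    tk <- Tj * (pi + 2 * pi * k - offsets[j]) / (2 * pi)
    tk <- tk[tk >= 0 & tk <= duration]
    data.frame(id = rep(j, length(tk)), peak_time_s = tk)
  })

  truth <- structure(list(
    centers = data.frame(id = seq_len(cfg$n_wavers),
                         x = centers[, 1], y = centers[, 2] - arm,
                         body_x = centers[, 1], body_y = centers[, 2]),
    peaks = if (cfg$n_wavers > 0) do.call(rbind, peaks)
            else data.frame(id = integer(0), peak_time_s = numeric(0)),
    period_s = cfg$wave_period_s,
    phase_offset = offsets,
    config = cfg
  ), class = "GroundTruth")

  list(frames = frame_sequence(frames, cfg$frame_rate, cfg$metric_scale),
       truth = truth)
}

#' Planted phases of the generated wavers
#'
#' The ground-truth phase of each waver at the queried times, under the
#' same convention as the recovery pipeline: zero at each planted peak,
#' linear in time in between, undefined outside \[first peak, last peak\].
#'
#' @param truth A `GroundTruth` from [generate_scene()].
#' @param times Numeric vector of times, seconds.
#' @return Matrix (length(times) x n_wavers) of phases in \[0, 2*pi) or NA.
#' @export
planted_phase <- function(truth, times) {
  n <- nrow(truth$centers)
  out <- matrix(NA_real_, length(times), n)
  for (j in seq_len(n)) {
    pk <- truth$peaks$peak_time_s[truth$peaks$id == j]
    if (length(pk) >= 2)
      out[, j] <- interpolate_phase(pk, times)$phase_rad
  }
  out
}

#' Planted group synchrony over time
#'
#' The Kuramoto order parameter of the planted phases — the recovery
#' target for the end-to-end pipeline.
#'
#' @inheritParams planted_phase
#' @return Numeric vector of R values (NA where fewer than 2 wavers have a
#'   defined phase).
#' @export
planted_sync <- function(truth, times) {
  if (nrow(truth$centers) < 2) stop("planted_sync needs >= 2 wavers")
  ph <- planted_phase(truth, times)
  vapply(seq_along(times), function(i) kuramoto_R(ph[i, ]), 0)
}

#' Write a scene to disk as numbered PNG frames plus ground truth
#'
#' Writes `frame_000001.png`, ..., a `frames_meta.yaml` with the frame
#' rate (and metric scale if any), and two CSVs: `truth_centers.csv`
#' (`id,x,y`) and `truth_peaks.csv` (`id,peak_time_s`).
#'
#' @param scene Result of [generate_scene()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- scene$frames
  for (i in seq_along(fs$frames))
    png::writePNG(fs$frames[[i]],
                  file.path(dir, sprintf("frame_%06d.png", i)))
  meta <- list(frame_rate = fs$frame_rate)
  if (!is.null(fs$metric_scale)) meta$metric_scale <- fs$metric_scale
  yaml::write_yaml(meta, file.path(dir, "frames_meta.yaml"))
  utils::write.csv(scene$truth$centers, file.path(dir, "truth_centers.csv"),
                   row.names = FALSE)
  utils::write.csv(scene$truth$peaks, file.path(dir, "truth_peaks.csv"),
                   row.names = FALSE)
  invisible(dir)
}
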