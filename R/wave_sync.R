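# From per-ID claw-speed traces to wave events, oscillator phases, and
# group synchrony. Each crab is treated as an oscillator whose phase is
# zero at the moment of maximum claw speed in every wave cycle; phases are
# linearly interpolated between successive peaks and are undefined outside
# the period of active waving.

#' Centered moving-average smoothing
#'
#' Smooths a speed trace with an odd centered window; near the edges the
#' window shrinks symmetrically so the output has the same length as the
#' input and a constant series is preserved.
#'
#' @param x Numeric series.
#' @param window Odd window length in samples (>= 1, <= length(x)).
#' @return Smoothed series, same length as `x`.
#' @export
smooth_series <- function(x, window = 5) {
  n <- length(x)
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (window > n) stop("window (", window, ") exceeds series length (", n, ")")
  if (window == 1) return(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# prominence of a local maximum: height above the higher of the two bases,
# where each base is the minimum between the peak and the nearest
# strictly-higher sample on that side (or the series end).
peak_prominence <- function(x, i) {
  left <- x[seq_len(i - 1L)]
  higher_l <- which(left > x[i])
  lbase <- min(x[(if (length(higher_l)) max(higher_l) else 1L):i])
  right <- x[i:length(x)]
  higher_r <- which(right > x[i])
  rbase <- min(x[i:(if (length(higher_r)) i + min(higher_r) - 1L
                    else length(x))])
  x[i] - max(lbase, rbase)
}

#' Detect wave peaks in a smoothed speed trace
#'
#' Local maxima with prominence at least `min_prominence`, thinned so that
#' retained peaks are at least `min_separation` samples apart; when two
#' candidates conflict the higher one is kept (ties to the earlier).
#' Plateau maxima report their first sample.
#'
#' @param x Numeric series (typically from [smooth_series()]).
#' @param min_prominence Minimum peak prominence, same units as `x`.
#' @param min_separation Minimum spacing between kept peaks, samples (>= 1).
#' @return Increasing integer vector of peak indices (1-based); may be
#'   empty.
#' @export
detect_peaks <- function(x, min_prominence = 0, min_separation = 1) {
  stopifnot(min_separation >= 1)
  n <- length(x)
  if (n < 3) return(integer(0))
  # local maxima; plateaus collapse to their first sample
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(k) peak_prominence(x, k), 0)
  cand <- cand[prom >= min_prominence]
  if (length(cand) == 0) return(integer(0))
  # greedy thinning, highest first (earlier index wins ties)
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (k in ord) {
    if (all(abs(kept - k) >= min_separation)) kept <- c(kept, k)
  }
  sort(kept)
}

#' Interpolate oscillator phase between wave peaks
#'
#' Phase is zero at each peak and advances linearly to 2*pi at the next
#' peak; it is undefined (NA) before the first and after the last peak —
#' outside the period of active waving.
#'
#' @param peak_times Strictly increasing peak times, seconds.
#' @param query_times Times at which to evaluate the phase, seconds.
#' @return A `PhaseSeries`: data frame with `time_s`, `phase_rad` in
#'   \[0, 2*pi) or `NA`, and logical `active`.
#' @export
interpolate_phase <- function(peak_times, query_times) {
  if (is.unsorted(peak_times, strictly = TRUE))
    stop("peak_times must be strictly increasing")
  phase <- rep(NA_real_, length(query_times))
  if (length(peak_times) < 2) {
    warning("fewer than 2 peaks: phase is undefined everywhere")
  } else {
    inside <- query_times >= peak_times[1] &
      query_times <= peak_times[length(peak_times)]
    k <- findInterval(query_times[inside], peak_times,
                      rightmost.closed = TRUE)
    t0 <- peak_times[k]
    t1 <- peak_times[k + 1L]
    phase[inside] <- (2 * pi * (query_times[inside] - t0) / (t1 - t0)) %%
      (2 * pi)
  }
  data.frame(time_s = query_times, phase_rad = phase, active = !is.na(phase))
}

#' Kuramoto order parameter
#'
#' R = | mean_j exp(i * theta_j) |: 1 for perfectly aligned phases, near 0
#' for incoherent ones. Defined for at least two phases; `NA` values are
#' dropped first.
#'
#' @param phases Numeric vector of phases in radians.
#' @return R in \[0, 1\], or `NA` if fewer than 2 phases are defined.
#' @examples
#' kuramoto_R(c(0, 0, pi))  # 1/3
#' @export
kuramoto_R <- function(phases) {
  phases <- phases[!is.na(phases)]
  if (length(phases) < 2) return(NA_real_)
  Mod(mean(exp(1i * phases)))
}

#' Chance-level Kuramoto R for independent oscillators
#'
#' Monte-Carlo estimate of E\[R\] for `n` independent phases uniform on the
#' circle — the synchrony expected by chance for a group of that size
#' (2/pi for n = 2, ~ sqrt(pi)/(2 sqrt(n)) for large n).
#'
#' @param n Number of oscillators (>= 2).
#' @param reps Monte-Carlo draws (>= 1).
#' @param seed Optional integer seed, making the estimate reproducible
#'   without disturbing the caller's RNG state.
#' @return Mean R over the draws.
#' @export
chance_level_R <- function(n, reps = 10000, seed = NULL) {
  stopifnot(n >= 2, reps >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  mean(vapply(seq_len(reps),
              function(i) Mod(mean(exp(1i * stats::runif(n, 0, 2 * pi)))),
              0))
}

# Energy-centroid refinement of a wave-peak time: the moment of maximum
# claw speed estimated as the centroid of the smoothed speed envelope
# (above its local base) within +-halfwin samples of the detected peak.
# Equals the argmax for a clean symmetric peak; robust when the measured
# envelope is locally distorted (e.g. double-humped) around the true
# maximum. halfwin should not exceed the minimum peak separation.
refine_peak_times <- function(sm, times, peaks, halfwin) {
  vapply(peaks, function(i) {
    lo <- max(1L, i - halfwin)
    hi <- min(length(sm), i + halfwin)
    w <- sm[lo:hi] - min(sm[lo:hi])
    if (sum(w) <= 0) return(times[i])
    sum(times[lo:hi] * w) / sum(w)
  }, 0)
}

#' Wave and synchrony analysis of a TrackSet
#'
#' For every track: fill its speed trace onto a contiguous frame grid,
#' smooth, detect wave peaks, refine each peak time to the energy centroid
#' of the surrounding speed envelope, and interpolate phase. Then, on the
#' common time grid, compute the Kuramoto order parameter over all IDs
#' actively waving at each instant, its time average `mean_R`, and a
#' Monte-Carlo chance baseline matched to the observed group sizes.
#'
#' @param tracks A `TrackSet` from [run_tracking()] (typically after
#'   [filter_tracks()]).
#' @param config Pipeline configuration; wave and sync settings are used.
#' @return List with elements `phases` (data frame `time_s`, `id`,
#'   `phase_rad`, `active`), `peaks` (data frame `id`, `peak_time_s`),
#'   `sync` (data frame `time_s`, `n_active`, `R`), and `summary` (list
#'   `mean_R`, `chance_R`, `n_ids`, `n_waves`).
#' @export
analyze_tracks <- function(tracks, config = tracks$config) {
  stopifnot(inherits(tracks, "TrackSet"))
  fps <- tracks$frame_rate
  prom <- config$wave$min_prominence %||% config$grid$speed_cutoff
  sep <- max(1L, round(config$wave$min_separation_s * fps))
  grid_frames <- seq.int(0L, tracks$n_frames - 2L)  # one per frame pair
  grid_times <- (grid_frames + 0.5) / fps

  phases <- list(); peaks <- list()
  phase_mat <- matrix(NA_real_, length(grid_times), length(tracks$tracks))
  n_waves <- 0L
  for (j in seq_along(tracks$tracks)) {
    tr <- tracks$tracks[[j]]
    ss <- track_speed_series(tr, fps)
    w <- config$wave$smooth_window
    w <- min(w, if (length(ss$speed) %% 2 == 0) length(ss$speed) - 1L
             else length(ss$speed))
    if (w < 1) next
    sm <- smooth_series(ss$speed, w)
    pk <- detect_peaks(sm, prom, sep)
    pk_t <- refine_peak_times(sm, ss$time_s, pk, sep)
    if (is.unsorted(pk_t, strictly = TRUE)) pk_t <- ss$time_s[pk]
    n_waves <- n_waves + max(length(pk) - 1L, 0L)
    peaks[[j]] <- data.frame(id = rep(tr$id, length(pk_t)),
                             peak_time_s = pk_t)
    ph <- if (length(pk_t) >= 2)
      interpolate_phase(pk_t, grid_times)
    else
      data.frame(time_s = grid_times, phase_rad = NA_real_, active = FALSE)
    phase_mat[, j] <- ph$phase_rad
    phases[[j]] <- cbind(id = tr$id, ph)[, c("time_s", "id", "phase_rad",
                                             "active")]
  }

  n_active <- rowSums(!is.na(phase_mat))
  R_t <- vapply(seq_along(grid_times),
                function(i) kuramoto_R(phase_mat[i, ]), 0)
  sync <- data.frame(time_s = grid_times, n_active = n_active, R = R_t)
  mean_R <- if (any(!is.na(R_t))) mean(R_t, na.rm = TRUE) else NA_real_

  # chance baseline matched to the distribution of observed group sizes
  counts <- table(n_active[n_active >= 2])
  chance_R <- if (length(counts) > 0) {
    per_n <- vapply(as.integer(names(counts)), function(nn)
      chance_level_R(nn, config$sync$chance_reps, config$sync$seed), 0)
    sum(per_n * as.vector(counts)) / sum(counts)
  } else NA_real_

  list(
    phases = if (length(phases)) do.call(rbind, phases)
             else data.frame(time_s = numeric(0), id = integer(0),
                             phase_rad = numeric(0), active = logical(0)),
    peaks = if (length(peaks)) do.call(rbind, peaks)
            else data.frame(id = integer(0), peak_time_s = numeric(0)),
    sync = sync,
    summary = list(mean_R = mean_R, chance_R = chance_R,
                   n_ids = length(tracks$tracks), n_waves = n_waves)
  )
}
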