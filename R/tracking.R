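# Persistent-ID tracking: cluster centroids in each frame are matched to
# existing tracks by Euclidean distance under a maximum-displacement
# threshold, and unmatched centroids found new IDs.

#' Fresh tracking state
#'
#' @return An empty track state for [match_ids()].
#' @export
new_track_state <- function() {
  list(tracks = list(), next_id = 1L)
}

#' Match cluster centroids to existing tracks
#'
#' One step of centroid tracking. Candidate (track, cluster) pairs are
#' accepted greedily in order of increasing Euclidean distance between the
#' track's last position and the cluster centroid — so contested clusters
#' resolve deterministically and no track or cluster is used twice — and a
#' pair is rejected outright beyond `max_dist`. Unmatched clusters start
#' new IDs; a track unmatched for `patience` consecutive steps is closed
#' (an animal that leaves and re-enters gets a new ID).
#'
#' @param state Tracking state from [new_track_state()] or a previous call.
#' @param centroids Data frame from [cluster_centroids()] for this frame.
#' @param frame 0-based frame index being processed.
#' @param max_dist Maximum accepted match distance, px (> 0).
#' @param patience Consecutive unmatched steps before a track closes.
#' @return Updated state.
#' @export
match_ids <- function(state, centroids, frame, max_dist = 30, patience = 30) {
  stopifnot(max_dist > 0)
  active_idx <- which(vapply(state$tracks, function(tr) tr$active, TRUE))
  nc <- nrow(centroids)
  matched_track <- rep(FALSE, length(state$tracks))
  matched_clust <- rep(FALSE, max(nc, 0))

  if (length(active_idx) > 0 && nc > 0) {
    last_x <- vapply(state$tracks[active_idx], function(tr) tr$x[length(tr$x)], 0)
    last_y <- vapply(state$tracks[active_idx], function(tr) tr$y[length(tr$y)], 0)
    D <- outer(last_x, centroids$x, "-")^2 + outer(last_y, centroids$y, "-")^2
    ord <- order(D)  # column-major ties broken by (track, cluster) index
    lim <- max_dist^2
    for (o in ord) {
      if (D[o] > lim) break
      ti <- (o - 1) %% length(active_idx) + 1
      ci <- (o - 1) %/% length(active_idx) + 1
      gi <- active_idx[ti]
      if (matched_track[gi] || matched_clust[ci]) next
      matched_track[gi] <- TRUE
      matched_clust[ci] <- TRUE
      tr <- state$tracks[[gi]]
      tr$frames <- c(tr$frames, frame)
      tr$x <- c(tr$x, centroids$x[ci])
      tr$y <- c(tr$y, centroids$y[ci])
      tr$speed <- c(tr$speed, centroids$speed[ci])
      tr$misses <- 0L
      state$tracks[[gi]] <- tr
    }
  }

  # unmatched active tracks age toward closure
  for (gi in active_idx) {
    if (matched_track[gi]) next
    tr <- state$tracks[[gi]]
    tr$misses <- tr$misses + 1L
    if (tr$misses >= patience) tr$active <- FALSE
    state$tracks[[gi]] <- tr
  }

  # unmatched clusters spawn new IDs
  if (nc > 0) {
    for (ci in which(!matched_clust)) {
      state$tracks[[length(state$tracks) + 1L]] <- list(
        id = state$next_id, frames = frame,
        x = centroids$x[ci], y = centroids$y[ci],
        speed = centroids$speed[ci],
        misses = 0L, active = TRUE
      )
      state$next_id <- state$next_id + 1L
    }
  }
  state
}

#' Run the full tracking pipeline on a frame sequence
#'
#' For each consecutive frame pair: dense optical flow, grid downsampling,
#' magnitude thresholding, DBSCAN clustering of the surviving motion cells,
#' centroid computation, and ID matching against the previous frame's
#' tracks. A detection from the pair (t, t+1) is stamped with frame index t
#' and time (t + 0.5) / frame_rate, the midpoint of the interval the
#' displacement was measured over.
#'
#' @param frames A [frame_sequence()] (>= 2 frames).
#' @param config Pipeline configuration, see [default_config()].
#' @return A `TrackSet`: list with `tracks` (each carrying `id`, 0-based
#'   `frames`, centroid `x`, `y` in px, per-frame mean cluster `speed` in
#'   px/frame), `n_frames`, `frame_rate`, `metric_scale`, and the `config`
#'   snapshot.
#' @export
run_tracking <- function(frames, config = default_config()) {
  stopifnot(inherits(frames, "FrameSequence"))
  n <- length(frames$frames)
  fp <- flow_params(levels = config$flow$levels, winsize = config$flow$window,
                    iterations = config$flow$iterations)
  state <- new_track_state()
  pyr_a <- flow_pyramid(frames$frames[[1]], fp)
  for (t in seq_len(n - 1)) {
    pyr_b <- flow_pyramid(frames$frames[[t + 1]], fp)
    fl <- flow_between(pyr_a, pyr_b, fp)
    grid <- threshold_flow(downsample_flow(fl, config$grid$cell_size),
                           config$grid$speed_cutoff)
    mp <- motion_points(grid)
    labels <- if (nrow(mp) > 0)
      dbscan_points(mp, config$dbscan$epsilon, config$dbscan$minpts)
    else integer(0)
    cents <- cluster_centroids(mp, labels,
                               speed_stat = config$track$speed_stat %||% "max")
    state <- match_ids(state, cents, frame = t - 1L,
                       max_dist = config$track$max_distance,
                       patience = config$track$patience)
    if (isTRUE(config$verbose))
      message(sprintf("frame %d: %d motion cells, %d clusters, %d open tracks",
                      t - 1L, nrow(mp), nrow(cents),
                      sum(vapply(state$tracks, function(tr) tr$active, TRUE))))
    pyr_a <- pyr_b
  }

  tracks <- lapply(state$tracks, function(tr) {
    list(id = tr$id, frames = tr$frames, x = tr$x, y = tr$y,
         speed = tr$speed,
         first_frame = tr$frames[1], last_frame = tr$frames[length(tr$frames)])
  })
  structure(list(tracks = tracks, n_frames = n,
                 frame_rate = frames$frame_rate,
                 metric_scale = frames$metric_scale,
                 config = config),
            class = "TrackSet")
}

#' @export
print.TrackSet <- function(x, ...) {
  cat(sprintf("TrackSet: %d tracks over %d frames (%g fps)\n",
              length(x$tracks), x$n_frames, x$frame_rate))
  invisible(x)
}

#' Per-ID speed trace on a contiguous frame grid
#'
#' The track's mean cluster speed for every frame between its first and
#' last detection; frames where the track produced no supra-threshold
#' motion get speed 0 (the claw did not move measurably).
#'
#' @param track One element of a `TrackSet`'s `tracks` list.
#' @param frame_rate Frames per second, for the time stamps.
#' @return Data frame with `frame`, `time_s`, `speed`.
#' @export
track_speed_series <- function(track, frame_rate) {
  fr <- seq.int(track$first_frame, track$last_frame)
  sp <- numeric(length(fr))
  sp[match(track$frames, fr)] <- track$speed
  data.frame(frame = fr, time_s = (fr + 0.5) / frame_rate, speed = sp)
}

#' Keep only tracks showing complete claw waves
#'
#' Discards IDs that were not present for at least `min_full_waves` full
#' wave cycles. A full cycle is the interval between two successive
#' detected speed peaks, so a track with k peaks has k - 1 full waves;
#' transient noise blobs shorter than one wave period are removed.
#'
#' @param tracks A `TrackSet` from [run_tracking()].
#' @param min_full_waves Minimum complete wave cycles to retain a track.
#' @return The filtered `TrackSet`.
#' @export
filter_tracks <- function(tracks, min_full_waves = 1) {
  stopifnot(inherits(tracks, "TrackSet"))
  cfg <- tracks$config
  prom <- cfg$wave$min_prominence %||% cfg$grid$speed_cutoff
  sep <- max(1L, round(cfg$wave$min_separation_s * tracks$frame_rate))
  keep <- vapply(tracks$tracks, function(tr) {
    s <- track_speed_series(tr, tracks$frame_rate)$speed
    w <- min(cfg$wave$smooth_window, if (length(s) %% 2 == 0) length(s) - 1
             else length(s))
    if (w < 1) return(FALSE)
    pk <- detect_peaks(smooth_series(s, w), prom, sep)
    max(length(pk) - 1L, 0L) >= min_full_waves
  }, TRUE)
  tracks$tracks <- tracks$tracks[keep]
  tracks
}

#' Flatten a TrackSet to a tidy data frame
#'
#' One row per (frame, active ID): `frame`, `time_s`, `id`, `x_px`,
#' `y_px`, `x_m`, `y_m`, `speed_px_per_frame`. Metric columns are `NA`
#' when no meters-per-pixel calibration is configured.
#'
#' @param tracks A `TrackSet`.
#' @return Data frame ordered by frame then id.
#' @export
tracks_to_df <- function(tracks) {
  stopifnot(inherits(tracks, "TrackSet"))
  if (length(tracks$tracks) == 0)
    return(data.frame(frame = integer(0), time_s = numeric(0),
                      id = integer(0), x_px = numeric(0), y_px = numeric(0),
                      x_m = numeric(0), y_m = numeric(0),
                      speed_px_per_frame = numeric(0)))
  df <- do.call(rbind, lapply(tracks$tracks, function(tr) {
    data.frame(frame = tr$frames, time_s = (tr$frames + 0.5) / tracks$frame_rate,
               id = tr$id, x_px = tr$x, y_px = tr$y,
               speed_px_per_frame = tr$speed)
  }))
  ms <- tracks$metric_scale
  df$x_m <- if (is.null(ms)) NA_real_ else df$x_px * ms
  df$y_m <- if (is.null(ms)) NA_real_ else df$y_px * ms
  df <- df[, c("frame", "time_s", "id", "x_px", "y_px", "x_m", "y_m",
               "speed_px_per_frame")]
  df[order(df$frame, df$id), , drop = FALSE]
}
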