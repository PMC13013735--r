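# Pipeline configuration: every user-specified parameter of the method in
# one nested list, with documented defaults.

#' Default pipeline configuration
#'
#' Returns the full nested configuration consumed by [run_tracking()],
#' [analyze_tracks()] and the command-line interface. Parameters whose
#' values come from the method itself: `dbscan$epsilon = 30` px and
#' `dbscan$minpts = 2` (motion-cell points per cluster). The remaining
#' defaults are this package's documented choices:
#'
#' * `flow`: 3 pyramid levels, 15 px window, 3 iterations — the
#'   polynomial-expansion method's canonical settings.
#' * `grid`: `cell_size = 4` px — about half the apparent claw patch, so the
#'   patch core fills at least one cell at any grid alignment; `speed_cutoff
#'   = 0.2` px/frame, above the largest cell speed
#'   background pixel noise alone produces at the generator's default noise
#'   level, so a noise-only scene yields zero motion cells.
#' * `track`: `max_distance = 30` px (the centroid matching threshold, on
#'   the same spatial scale as epsilon), `patience = 30` frames (one typical wave
#'   period at 30 fps) before an unmatched ID is closed — an actively waving
#'   individual cannot stay below the motion threshold longer than one full
#'   cycle, so an ID survives the quiet stretch between flicks;
#'   `speed_stat = "max"`, the per-frame track speed summary (see
#'   [cluster_centroids()]), `min_full_waves = 1` for track filtering.
#' * `wave`: smoothing window 5 frames; peak prominence defaulting to the
#'   grid speed cutoff; minimum peak separation 0.5 s — longer than the
#'   measured flick envelope (so a wave cannot be double-counted when its
#'   speed profile is double-humped) yet far above any real wave rate.
#' * `sync`: 10^4 Monte-Carlo draws for the chance-level baseline.
#'
#' @return Nested named list of configuration values.
#' @export
default_config <- function() {
  list(
    video = list(start_frame = 0, frame_count = Inf,
                 frame_rate = NULL, metric_scale = NULL),
    flow = list(levels = 3, window = 15, iterations = 3),
    grid = list(cell_size = 4, speed_cutoff = 0.2),
    dbscan = list(epsilon = 30, minpts = 2),
    track = list(max_distance = 30, patience = 30, min_full_waves = 1,
                 speed_stat = "max"),
    wave = list(smooth_window = 5, min_prominence = NULL,
                min_separation_s = 0.5),
    sync = list(chance_reps = 10000, seed = 1),
    verbose = FALSE
  )
}

# recursive merge: values in `over` replace values in `base`
merge_config <- function(base, over) {
  for (k in names(over)) {
    if (is.list(over[[k]]) && is.list(base[[k]]))
      base[[k]] <- merge_config(base[[k]], over[[k]])
    else
      base[[k]] <- over[[k]]
  }
  base
}

#' Load a pipeline configuration
#'
#' Starts from [default_config()], overlays an optional YAML file, then an
#' optional list of overrides (deepest-wins recursive merge).
#'
#' @param path Optional YAML configuration file.
#' @param overrides Optional nested list of values taking precedence.
#' @return Nested configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  merge_config(cfg, overrides)
}
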