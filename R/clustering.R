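# Density-based clustering of thresholded motion points into individuals.
#
# DBSCAN is implemented here directly (classic Ester et al. semantics)
# rather than delegated, so its behavior — in particular the
# order-dependent assignment of border points — is fixed and reproducible:
# points are visited in their input order (row-major grid order for motion
# points), expansion is breadth-first, and minpts counts the point itself.

#' Cluster motion points with DBSCAN
#'
#' Groups 2-D points into density-connected clusters: a point with at least
#' `minpts` neighbors within radius `epsilon` (itself included) is a core
#' point; clusters grow from core points by density reachability; points
#' reachable from no core point are labeled noise. Euclidean distance.
#'
#' The defaults epsilon = 30 px and minpts = 2 suit field footage where
#' each animal occupies only a handful of motion cells.
#'
#' @param points Data frame or matrix with columns `x`, `y` (px). Row order
#'   is the visiting order and is part of the contract.
#' @param epsilon Neighborhood search radius in pixels (> 0).
#' @param minpts Minimum neighborhood size for a core point, counting the
#'   point itself (>= 1).
#' @return Integer vector of cluster labels aligned with the rows of
#'   `points`: 1, 2, ... for clusters, 0 for noise. Empty input gives an
#'   empty vector.
#' @export
dbscan_points <- function(points, epsilon = 30, minpts = 2) {
  stopifnot(epsilon > 0, minpts >= 1)
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  n <- nrow(pts)
  labels <- integer(n)
  if (n == 0) return(labels)

  D <- as.matrix(stats::dist(pts))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= epsilon))
  is_core <- lengths(nb) >= minpts

  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    if (!is_core[i]) next        # noise unless later claimed as border
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue) > 0) {
      q <- queue[1]
      queue <- queue[-1]
      if (!visited[q]) {
        visited[q] <- TRUE
        if (is_core[q])
          queue <- c(queue, setdiff(nb[[q]], q))
      }
      if (labels[q] == 0L) labels[q] <- cl
    }
  }
  labels
}

#' Centroids of point clusters
#'
#' Arithmetic mean position of each cluster's members; noise points are
#' excluded. When the points carry a `speed` column a per-cluster speed
#' summary is returned too (used as the track's claw-speed signal):
#' `"max"` takes the fastest member cell — the one dominated by the moving
#' claw, insensitive to how many partially-covered cells the grid happens
#' to include — while `"mean"` averages all member cells.
#'
#' @param points Data frame with columns `x`, `y` and optionally `speed`.
#' @param labels Cluster labels from [dbscan_points()], aligned with rows.
#' @param speed_stat How to summarize member cell speeds: `"max"`
#'   (default) or `"mean"`.
#' @return Data frame with one row per cluster: `cluster`, `x`, `y`,
#'   `size`, and `speed` (`NA` if unavailable).
#' @export
cluster_centroids <- function(points, labels, speed_stat = c("max", "mean")) {
  speed_stat <- match.arg(speed_stat)
  stat <- if (speed_stat == "max") max else mean
  points <- as.data.frame(points)
  if (nrow(points) != length(labels))
    stop("labels must align with points")
  keep <- labels > 0
  if (!any(keep))
    return(data.frame(cluster = integer(0), x = numeric(0), y = numeric(0),
                      size = integer(0), speed = numeric(0)))
  lab <- labels[keep]
  sp <- if ("speed" %in% names(points)) points$speed[keep] else NA_real_
  agg <- data.frame(
    cluster = sort(unique(lab)),
    x = as.vector(tapply(points$x[keep], lab, mean)),
    y = as.vector(tapply(points$y[keep], lab, mean)),
    size = as.vector(tapply(rep(1L, sum(keep)), lab, sum)),
    speed = if (all(is.na(sp))) NA_real_ else as.vector(tapply(sp, lab, stat))
  )
  rownames(agg) <- NULL
  agg
}
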