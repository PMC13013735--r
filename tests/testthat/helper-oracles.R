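# Independent reference implementations used as test oracles.

# Brute-force DBSCAN, written as a direct transliteration of the original
# pseudocode: explicit region queries recomputed on the fly, seed-set
# expansion, points visited in index order. 0 = noise.
brute_dbscan <- function(pts, eps, minpts) {
  n <- nrow(pts)
  region_query <- function(i) {
    which(sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2) <= eps)
  }
  labels <- rep(NA_integer_, n)  # NA = unclassified
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    seeds <- region_query(i)
    if (length(seeds) < minpts) {
      labels[i] <- 0L
      next
    }
    cl <- cl + 1L
    # assign unclassified or noise seeds; border points already claimed
    # by an earlier cluster keep their label (classic semantics)
    for (k in seeds)
      if (is.na(labels[k]) || labels[k] == 0L) labels[k] <- cl
    seeds <- setdiff(seeds, i)
    while (length(seeds) > 0) {
      j <- seeds[1]
      seeds <- seeds[-1]
      res <- region_query(j)
      if (length(res) >= minpts) {
        for (k in res) {
          if (is.na(labels[k]) || labels[k] == 0L) {
            if (is.na(labels[k])) seeds <- c(seeds, k)
            labels[k] <- cl
          }
        }
      }
    }
  }
  labels[is.na(labels)] <- 0L
  labels
}

# TRUE if two labelings induce the same partition (noise must coincide;
# cluster ids may be permuted)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  key_a <- match(a, unique(a[a != 0L]))
  key_b <- match(b, unique(b[b != 0L]))
  identical(key_a, key_b)
}

# smooth random texture base for flow tests (built independently of the
# package's own image utilities)
texture_base <- function(n, seed = 1) {
  set.seed(seed)
  f <- matrix(runif(n * n), n, n)
  k <- stats::dnorm(-4:4, sd = 1.5)
  k <- k / sum(k)
  g <- apply(f, 2, function(col) as.numeric(stats::filter(col, k, sides = 2)))
  g <- t(apply(t(g), 2,
               function(col) as.numeric(stats::filter(col, k, sides = 2))))
  g[is.na(g)] <- 0.5
  g
}

# frame pair where the content of frame b is frame a translated by
# (dx, dy) pixels — the ground truth is exact by construction
shifted_pair <- function(n, dx, dy, seed = 1) {
  m <- 16L
  base <- texture_base(n + 2L * m, seed)
  a <- base[(m + 1):(m + n), (m + 1):(m + n)]
  b <- base[(m + 1 - dy):(m + n - dy), (m + 1 - dx):(m + n - dx)]
  list(a = a, b = b)
}

# a small standard test scene (kept light so unit tests stay fast)
small_scene <- function(n_wavers = 3, seed = 7, n_frames = 240,
                        noise_sigma = 0) {
  generate_scene(scene_config(width = 320, height = 240,
                              n_frames = n_frames, n_wavers = n_wavers,
                              noise_sigma = noise_sigma, seed = seed))
}

# map each track to the nearest ground-truth waver (by mean position)
match_tracks_to_truth <- function(tracks, truth) {
  vapply(tracks$tracks, function(tr) {
    d <- (truth$centers$x - mean(tr$x))^2 + (truth$centers$y - mean(tr$y))^2
    truth$centers$id[which.min(d)]
  }, integer(1))
}
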