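cents <- function(x, y, speed = 1) {
  data.frame(cluster = seq_along(x), x = x, y = y,
             size = rep(2L, length(x)),
             speed = rep(speed, length.out = length(x)))
}

test_that("a nearby cluster continues the same ID", {
  st <- new_track_state()
  st <- match_ids(st, cents(10, 10), frame = 0)
  st <- match_ids(st, cents(12, 10), frame = 1, max_dist = 30)
  expect_length(st$tracks, 1)
  expect_equal(st$tracks[[1]]$x, c(10, 12))
})

test_that("clusters beyond max_dist spawn new IDs", {
  st <- new_track_state()
  st <- match_ids(st, cents(10, 10), frame = 0)
  st <- match_ids(st, cents(100, 100), frame = 1, max_dist = 30)
  expect_length(st$tracks, 2)
  expect_equal(st$tracks[[1]]$frames, 0)     # old track unmatched
  expect_equal(st$tracks[[2]]$frames, 1)     # new ID for the far cluster
})

test_that("contested clusters resolve by globally smallest distance", {
  st <- new_track_state()
  st <- match_ids(st, cents(c(0, 10), c(0, 0)), frame = 0)
  # clusters at (4,0) and (6,0): pair (track1, (4,0)) has the globally
  # smallest distance 4, leaving (6,0) for track 2 at distance 4 —
  # this also minimizes the total distance over all one-to-one
  # assignments (4 + 4 = 8 vs 6 + 6 = 12), verified by enumeration
  st <- match_ids(st, cents(c(4, 6), c(0, 0)), frame = 1, max_dist = 30)
  expect_length(st$tracks, 2)
  expect_equal(st$tracks[[1]]$x, c(0, 4))
  expect_equal(st$tracks[[2]]$x, c(10, 6))
})

test_that("greedy matching is one-to-one and respects the threshold", {
  set.seed(12)
  for (rep in 1:25) {
    nt <- sample(1:5, 1); nc <- sample(1:5, 1)
    st <- new_track_state()
    st <- match_ids(st, cents(runif(nt, 0, 50), runif(nt, 0, 50)), frame = 0)
    st <- match_ids(st, cents(runif(nc, 0, 50), runif(nc, 0, 50)),
                    frame = 1, max_dist = 20)
    # no cluster claimed twice: every track extended to frame 1 took a
    # distinct position, and every consecutive step is within max_dist
    ext <- Filter(function(tr) length(tr$frames) == 2, st$tracks)
    pos <- vapply(ext, function(tr) tr$x[2] + 1i * tr$y[2], complex(1))
    expect_equal(length(pos), length(unique(pos)))
    for (tr in ext)
      expect_lte(sqrt(diff(tr$x)^2 + diff(tr$y)^2), 20)
  }
})

test_that("tracks close after `patience` unmatched frames", {
  st <- new_track_state()
  st <- match_ids(st, cents(10, 10), frame = 0, patience = 3)
  none <- cents(numeric(0), numeric(0))
  for (f in 1:3) st <- match_ids(st, none, frame = f, patience = 3)
  expect_false(st$tracks[[1]]$active)
  # a reappearing cluster gets a fresh ID
  st <- match_ids(st, cents(10, 10), frame = 4, patience = 3)
  expect_length(st$tracks, 2)
  expect_equal(st$tracks[[2]]$id, 2)
})

test_that("a static scene produces zero tracks", {
  scene <- generate_scene(scene_config(width = 96, height = 96,
                                       n_frames = 12, n_wavers = 0,
                                       noise_sigma = 0, seed = 3))
  ts <- run_tracking(scene$frames)
  expect_length(ts$tracks, 0)
  expect_equal(nrow(tracks_to_df(ts)), 0)
})

test_that("planted wavers are tracked with stable IDs at their centers", {
  scene <- small_scene(n_wavers = 3, seed = 7)
  ts <- run_tracking(scene$frames)
  tsf <- filter_tracks(ts)
  expect_length(tsf$tracks, 3)
  ids <- match_tracks_to_truth(tsf, scene$truth)
  expect_length(unique(ids), 3)
  # each track sits near its waver's motion center
  for (k in seq_along(tsf$tracks)) {
    tr <- tsf$tracks[[k]]
    ctr <- scene$truth$centers[scene$truth$centers$id == ids[k], ]
    expect_lt(sqrt((mean(tr$x) - ctr$x)^2 + (mean(tr$y) - ctr$y)^2),
              tsf$config$grid$cell_size + 2)
  }
  # consecutive steps respect the displacement bound
  for (tr in tsf$tracks) {
    d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    expect_true(all(d <= tsf$config$track$max_distance))
  }
})

test_that("tracking the same scene twice is bit-stable", {
  scene <- generate_scene(scene_config(width = 160, height = 120,
                                       n_frames = 40, n_wavers = 1,
                                       min_separation = 20,
                                       noise_sigma = 0.005, seed = 5))
  t1 <- run_tracking(scene$frames)
  t2 <- run_tracking(scene$frames)
  expect_identical(tracks_to_df(t1), tracks_to_df(t2))
})

test_that("filter_tracks removes IDs without a full wave", {
  scene <- small_scene(n_wavers = 3, seed = 11)
  ts <- run_tracking(scene$frames)
  tsf <- filter_tracks(ts, min_full_waves = 1)
  # every retained track shows at least two peaks (one full cycle)
  cfg <- tsf$config
  sep <- max(1, round(cfg$wave$min_separation_s * tsf$frame_rate))
  for (tr in tsf$tracks) {
    s <- track_speed_series(tr, tsf$frame_rate)$speed
    pk <- detect_peaks(smooth_series(s, 5), cfg$grid$speed_cutoff, sep)
    expect_gte(length(pk), 2)
  }
  # an absurd requirement removes everything
  expect_length(filter_tracks(ts, min_full_waves = 1000)$tracks, 0)
})

test_that("tracks_to_df carries metric coordinates when calibrated", {
  scene <- generate_scene(scene_config(width = 160, height = 120,
                                       n_frames = 40, n_wavers = 1,
                                       min_separation = 20, noise_sigma = 0,
                                       metric_scale = 0.001, seed = 5))
  df <- tracks_to_df(run_tracking(scene$frames))
  expect_gt(nrow(df), 0)
  expect_equal(df$x_m, df$x_px * 0.001)
  expect_equal(df$time_s, (df$frame + 0.5) / 30)
})
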