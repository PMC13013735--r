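test_that("a waver-free noiseless scene is static", {
  sc <- generate_scene(scene_config(width = 64, height = 48, n_frames = 6,
                                    n_wavers = 0, noise_sigma = 0, seed = 2))
  for (i in 2:6)
    expect_identical(sc$frames$frames[[i]], sc$frames$frames[[1]])
})

test_that("planted peak times follow the period and offset", {
  # 90 frames at 30 fps, period 1 s, flick at t = 0: peaks at 0, 1, 2 s
  sc <- generate_scene(scene_config(width = 96, height = 96, n_frames = 90,
                                    n_wavers = 1, wave_period_s = 1,
                                    wave_phase_offset = pi,
                                    min_separation = 10,
                                    noise_sigma = 0, seed = 3))
  pk <- sc$truth$peaks$peak_time_s
  expect_equal(pk, c(0, 1, 2))

  # the rendered claw's fastest frame pairs cluster around the planted
  # peaks: pair k covers 0-based frames (k-1, k), midpoint (k-0.5)/30 s
  fr <- sc$frames$frames
  d <- vapply(2:90, function(i) max(abs(fr[[i]] - fr[[i - 1]])), 0)
  top <- order(-d)[1:3]
  for (k in top)
    expect_lt(min(abs((k - 0.5) / 30 - pk)), 0.1)
})

test_that("the same config and seed reproduce bit-identical frames", {
  cfg <- scene_config(width = 220, height = 140, n_frames = 8, n_wavers = 2,
                      min_separation = 30, noise_sigma = 0.01, seed = 13)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$frames$frames, b$frames$frames)
  expect_identical(a$truth$peaks, b$truth$peaks)
  # a different seed gives different frames
  cfg2 <- scene_config(width = 220, height = 140, n_frames = 8, n_wavers = 2,
                       min_separation = 30, noise_sigma = 0.01, seed = 14)
  expect_false(identical(generate_scene(cfg2)$frames$frames,
                         a$frames$frames))
})

test_that("scene generation leaves the caller's RNG stream untouched", {
  set.seed(99); x1 <- runif(1)
  set.seed(99)
  invisible(generate_scene(scene_config(width = 140, height = 120,
                                        n_frames = 3, n_wavers = 1,
                                        min_separation = 10, seed = 5)))
  expect_equal(runif(1), x1)
})

test_that("waver placement respects separation and frame bounds", {
  cfg <- scene_config(width = 480, height = 360, n_frames = 2, n_wavers = 10,
                      noise_sigma = 0, seed = 21)
  sc <- generate_scene(cfg)
  ctr <- sc$truth$centers
  d <- as.matrix(dist(cbind(ctr$body_x, ctr$body_y)))
  diag(d) <- Inf
  expect_gte(min(d), cfg$min_separation)
  expect_true(all(ctr$body_x > 0 & ctr$body_x < 480 &
                  ctr$body_y > 0 & ctr$body_y < 360))
  # infeasible packing errors out
  expect_error(generate_scene(scene_config(width = 100, height = 100,
                                           n_frames = 2, n_wavers = 10,
                                           seed = 1)),
               "infeasible")
})

test_that("planted synchrony follows the Kuramoto identities", {
  mk <- function(offsets) {
    generate_scene(scene_config(width = 320, height = 240, n_frames = 150,
                                n_wavers = length(offsets),
                                wave_phase_offset = offsets,
                                noise_sigma = 0, seed = 6))$truth
  }
  t_q <- c(1.6, 1.8, 2.0)
  expect_equal(planted_sync(mk(rep(1, 3)), t_q), rep(1, 3))
  expect_equal(planted_sync(mk(c(0, pi/2, pi, 3*pi/2)), t_q), rep(0, 3),
               tolerance = 1e-12)
  expect_equal(planted_sync(mk(c(0, 0, pi)), t_q), rep(1/3, 3),
               tolerance = 1e-12)
})

test_that("duty cycles below one freeze the claw between flicks", {
  mk <- function(duty) {
    generate_scene(scene_config(width = 96, height = 96, n_frames = 61,
                                n_wavers = 1, wave_period_s = 2,
                                wave_phase_offset = pi, duty_cycle = duty,
                                min_separation = 10, noise_sigma = 0,
                                seed = 4))
  }
  moving <- function(sc) {
    fr <- sc$frames$frames
    sum(vapply(2:61, function(i) max(abs(fr[[i]] - fr[[i - 1]])) > 1e-6,
               TRUE))
  }
  expect_lt(moving(mk(0.4)), moving(mk(1.0)))
  expect_equal(moving(mk(1.0)), 60)
})
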