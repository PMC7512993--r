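small_geom <- sensor_geometry(32, 32)

test_that("frame rendering matches the geometric definition", {
  # static disc: all frames identical; pixel count close to pi r^2
  spec <- stimulus_spec(
    center_traj = data.frame(t_us = c(0, 1e5), cx = 64, cy = 64),
    size_traj = data.frame(t_us = c(0, 1e5), radius = 10))
  fr <- render_frames(spec)
  expect_length(fr$frames, 11)
  for (f in fr$frames) expect_identical(f, fr$frames[[1]])
  dark <- sum(fr$frames[[1]] == spec$object_level)
  expect_lt(abs(dark - pi * 100), 2 * pi * 10)  # within a 1-px annulus

  # independent check of the disc inequality on the rendered frame
  xs <- matrix(rep(0:127, each = 128), 128)
  ys <- matrix(rep(0:127, times = 128), 128)
  expect_identical(fr$frames[[1]] == spec$object_level,
                   (xs - 64)^2 + (ys - 64)^2 < 100)

  # zero radius: uniform background everywhere, with a warning
  spec0 <- stimulus_spec(
    center_traj = data.frame(t_us = c(0, 1e5), cx = 64, cy = 64),
    size_traj = data.frame(t_us = c(0, 1e5), radius = 0))
  expect_warning(fr0 <- render_frames(spec0), "never intersects")
  expect_true(all(vapply(fr0$frames,
                         function(f) all(f == spec0$background_level), TRUE)))
})

test_that("pixel memory emits one event per full threshold step", {
  # identical consecutive frames: silence
  f <- matrix(1, 4, 4)
  seq_same <- structure(list(times_us = c(0, 1000), frames = list(f, f),
                             geometry = sensor_geometry(4, 4)),
                        class = "frame_sequence")
  expect_equal(n_events(frames_to_events(seq_same, 0.3)), 0)

  # a drop of exactly 2 * threshold at one pixel: exactly two OFF events
  theta <- 0.3
  f2 <- f
  f2[3, 2] <- exp(log(1) - 2 * theta)  # pixel x=1, y=2
  seq_drop <- structure(list(times_us = c(0, 1000), frames = list(f, f2),
                             geometry = sensor_geometry(4, 4)),
                        class = "frame_sequence")
  ev <- frames_to_events(seq_drop, theta)$events
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$polarity == "OFF"))
  expect_true(all(ev$x == 1 & ev$y == 2 & ev$t == 1000))
})

test_that("event polarity always matches the sign of the intensity change", {
  spec <- stimulus_spec(
    center_traj = data.frame(t_us = c(0, 1e5), cx = 15.5, cy = 15.5),
    size_traj = data.frame(t_us = c(0, 1e5), radius = c(3, 12)))
  fr <- render_frames(spec, small_geom)
  s <- frames_to_events(fr, spec$threshold)
  expect_gt(n_events(s), 0)
  expect_true(all(s$events$polarity == "OFF"))  # expanding dark disc
  # each event's pixel really darkened between its frame and the previous
  for (i in seq_len(n_events(s))) {
    k <- match(s$events$t[i], fr$times_us)
    d <- fr$frames[[k]][s$events$y[i] + 1, s$events$x[i] + 1] -
      fr$frames[[k - 1]][s$events$y[i] + 1, s$events$x[i] + 1]
    expect_lt(d, 0)
  }
})

test_that("motion archetypes have the expected polarity balance", {
  ap <- make_stimulus("approach", small_geom, duration_us = 1e5,
                      r_start = 3, r_end = 12, center = c(15.5, 15.5))
  re <- make_stimulus("recede", small_geom, duration_us = 1e5,
                      r_start = 3, r_end = 12, center = c(15.5, 15.5))
  la <- make_stimulus("lateral", small_geom, duration_us = 1e5,
                      r_start = 5, r_end = 5, center = c(15.5, 15.5),
                      px_per_frame = 1)
  n_off <- function(s) sum(s$events$polarity == "OFF")
  n_on <- function(s) sum(s$events$polarity == "ON")
  expect_gt(n_off(ap), n_on(ap))   # contour only darkens
  expect_gt(n_on(re), n_off(re))   # mirror case
  expect_equal(n_off(la), n_on(la))  # rigid translation is symmetric
  expect_gt(n_off(la), 0)
})

test_that("time-reversing a stimulus swaps ON and OFF counts exactly", {
  mk <- function(radii) {
    spec <- stimulus_spec(
      center_traj = data.frame(t_us = c(0, 8e4), cx = 15.5, cy = 15.5),
      size_traj = data.frame(t_us = seq(0, 8e4, length.out = length(radii)),
                             radius = radii))
    frames_to_events(render_frames(spec, small_geom), spec$threshold)
  }
  radii <- c(2, 7, 4, 12, 9)
  fwd <- mk(radii)
  rev_ <- mk(rev(radii))
  tab <- function(s) c(off = sum(s$events$polarity == "OFF"),
                       on = sum(s$events$polarity == "ON"))
  expect_equal(unname(tab(fwd)), unname(rev(tab(rev_))))
})

test_that("event count is non-increasing in the sensor threshold", {
  spec_at <- function(theta) {
    s <- stimulus_spec(
      center_traj = data.frame(t_us = c(0, 1e5), cx = 15.5, cy = 15.5),
      size_traj = data.frame(t_us = c(0, 1e5), radius = c(2, 12)),
      threshold = theta)
    n_events(frames_to_events(render_frames(s, small_geom), theta))
  }
  counts <- vapply(c(0.15, 0.3, 0.5, 0.8), spec_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
})

test_that("timestamp jitter is seeded and bounded", {
  mk <- function() make_stimulus("approach", small_geom, duration_us = 1e5,
                                 r_start = 3, r_end = 12,
                                 center = c(15.5, 15.5), jitter_us = 5000)
  set.seed(42); a <- mk()
  set.seed(42); b <- mk()
  expect_identical(a$events, b$events)
  base <- make_stimulus("approach", small_geom, duration_us = 1e5,
                        r_start = 3, r_end = 12, center = c(15.5, 15.5))
  expect_equal(n_events(a), n_events(base))
  expect_true(all(diff(a$events$t) >= 0))
})

test_that("approach_recede concatenation records its phase boundary", {
  s <- make_stimulus("approach_recede", small_geom, duration_us = 1e5,
                     r_start = 3, r_end = 12, center = c(15.5, 15.5),
                     gap_us = 3e4)
  expect_equal(s$metadata$phase_boundary_us, 1.3e5)
  expect_equal(s$metadata$period_us, 2.6e5)
  t <- s$events$t
  pol <- s$events$polarity
  expect_true(all(pol[t <= 1e5] == "OFF"))
  expect_true(all(pol[t > 1.3e5] == "ON"))
  expect_equal(sum(t > 1e5 & t <= 1.3e5), 0)  # silent gap
  expect_error(make_stimulus("approach", duration_us = 5000), "degenerate")
})
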