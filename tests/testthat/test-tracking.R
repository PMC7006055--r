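test_that("calibration converts traced bar length to mm per pixel", {
  expect_equal(calibrate_scale(100)$mm_per_pixel, 0.1)
  expect_equal(calibrate_scale(200)$mm_per_pixel, 0.05)
  expect_error(calibrate_scale(0), "positive")
})

test_that("template tracker follows static and moving markers within 1 px", {
  # static marker: identical position in all frames
  n <- 8
  truth <- list(positions = list(m = cbind(x = rep(60, n), y = rep(40, n))))
  vid <- render_marker_video(truth, list(width_px = 96, height_px = 96, bar_length_px = 50))
  tr <- track_markers(vid, list(m = c(60, 40)))
  expect_equal(max(abs(tr$m$positions[, 1] - 60)), 0)
  expect_equal(max(abs(tr$m$positions[, 2] - 40)), 0)
  expect_true(all(tr$m$confidence > 0.9))

  # sinusoidally moving markers recovered within 1 px of generator truth
  g <- gen_jaw_trace(jaw_trace_spec(lick_rate_hz = 5, amplitude_mm = 1,
                                    baseline_mm = 2, duration_s = 1, seed = 2))
  vid <- render_marker_video(g$truth, list(width_px = 128, height_px = 128))
  tr <- track_markers(vid, list(upper = g$truth$positions$upper_jaw[1, ],
                                lower = g$truth$positions$lower_jaw[1, ]))
  expect_lt(max(abs(tr$lower$positions - g$truth$positions$lower_jaw)), 1)
  expect_lt(max(abs(tr$upper$positions - g$truth$positions$upper_jaw)), 1)
})

test_that("tracker reports a tracking-lost error when the marker escapes", {
  n <- 12
  xs <- 20 + 10 * (0:(n - 1))  # walks off the right edge
  truth <- list(positions = list(m = cbind(x = pmin(xs, 90), y = rep(48, n))))
  vid <- render_marker_video(truth, list(width_px = 96, height_px = 96, bar_length_px = 50))
  # erase the marker after frame 5 to break the match
  for (i in 7:n) vid[[i]][] <- 0.08
  expect_error(track_markers(vid, list(m = c(20, 48))), "tracking lost.*frame")
})

test_that("jaw gape trace equals per-frame marker distance times the scale", {
  n <- 10
  up <- marker_track(cbind(rep(0, n), rep(0, n)))
  lo <- marker_track(cbind(rep(0, n), rep(50, n)))
  g <- jaw_gape_trace(up, lo, calibrate_scale(100), fps = 30)
  expect_equal(g$values, rep(5, n))

  same <- jaw_gape_trace(up, up, calibrate_scale(100), fps = 30)
  expect_equal(same$values, rep(0, n))

  set.seed(5)
  a <- marker_track(matrix(runif(2 * n, 0, 100), ncol = 2))
  b <- marker_track(matrix(runif(2 * n, 0, 100), ncol = 2))
  sc <- calibrate_scale(137)
  got <- jaw_gape_trace(a, b, sc, fps = 30)$values
  want <- sapply(seq_len(n), function(i) {
    sqrt((a$positions[i, 1] - b$positions[i, 1])^2 +
           (a$positions[i, 2] - b$positions[i, 2])^2) * 10 / 137
  })
  expect_equal(got, unname(want))
  expect_error(jaw_gape_trace(up, marker_track(cbind(0, 0)), sc, 30), "same number")
})

test_that("glottal point adjustment moves the nearer point outward only", {
  adj <- adjust_glottal_points(c(-12, 0), c(10, 0), c(0, 0))
  expect_equal(adj$left, c(-12, 0))
  expect_equal(adj$right, c(12, 0))
  # distances equal after adjustment, along the original ray
  d <- function(p) sqrt(sum(p^2))
  adj2 <- adjust_glottal_points(c(-3, 8), c(5, 7), c(1, 1))
  expect_equal(d(adj2$left - c(1, 1)), d(adj2$right - c(1, 1)))

  # symmetric input unchanged; operation idempotent
  sym <- adjust_glottal_points(c(-5, 5), c(5, 5), c(0, 0))
  expect_equal(sym$left, c(-5, 5))
  expect_equal(sym$right, c(5, 5))
  again <- adjust_glottal_points(adj2$left, adj2$right, c(1, 1))
  expect_equal(again, adj2)

  expect_error(adjust_glottal_points(c(-1, 0), c(0, 0), c(0, 0)), "degenerate")
})

test_that("lateral traces are signed, symmetric, and axis-invariant", {
  g <- gen_glottal_traces(glottal_trace_spec(duration_s = 2, seed = 4))
  lt <- marker_track(g$truth$positions$left_glottal)
  rt <- marker_track(g$truth$positions$right_glottal)
  ct <- marker_track(g$truth$positions$dorsal_commissure)
  tr <- glottal_lateral_traces(lt, rt, ct, fps = 30)
  # symmetric anti-phase motion: equal magnitude, opposite sign per frame
  expect_equal(tr$left$values, -tr$right$values, tolerance = 1e-10)
  expect_true(all(tr$left$values < 0) && all(tr$right$values > 0))
  expect_equal(tr$width$values,
               g$truth$positions$right_glottal[, 1] -
                 g$truth$positions$left_glottal[, 1], tolerance = 1e-10)

  # static points give constant traces
  n <- 6
  st <- glottal_lateral_traces(
    marker_track(cbind(rep(-4, n), rep(0, n))),
    marker_track(cbind(rep(4, n), rep(0, n))),
    marker_track(cbind(rep(0, n), rep(10, n))), fps = 30)
  expect_equal(diff(range(st$width$values)), 0)

  # global rotation + translation of all three tracks leaves traces unchanged
  th <- 0.6; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(tk) marker_track(t(R %*% t(tk$positions)) +
                                     matrix(c(30, -12), nrow(tk$positions), 2, byrow = TRUE))
  tr2 <- glottal_lateral_traces(rot(lt), rot(rt), rot(ct), fps = 30)
  expect_equal(tr2$left$values, tr$left$values, tolerance = 1e-8)
  expect_equal(tr2$width$values, tr$width$values, tolerance = 1e-8)
})

test_that("width trace period matches the generator's respiratory period", {
  g <- gen_glottal_traces(glottal_trace_spec(respiratory_rate_per_min = 150,
                                             duration_s = 10))
  tr <- glottal_lateral_traces(marker_track(g$truth$positions$left_glottal),
                               marker_track(g$truth$positions$right_glottal),
                               marker_track(g$truth$positions$dorsal_commissure),
                               fps = 30)
  cyc <- detect_respiratory_cycles(tr$left, tr$right, tr$width)
  got <- cyc$width$max_times
  expect_equal(length(got), length(g$truth$cycle_max_times))
  expect_lt(max(abs(got - g$truth$cycle_max_times)), 1 / 30 + 1e-9)
})

test_that("frame PNG round trip preserves pixel data", {
  g <- gen_jaw_trace(jaw_trace_spec(duration_s = 0.2, seed = 3))
  vid <- render_marker_video(g$truth, list(width_px = 96, height_px = 96,
                                           bar_length_px = 50))
  d <- tempfile()
  write_frames_png(vid, d)
  back <- read_frames_png(d)
  expect_equal(length(back), length(vid))
  expect_lt(max(abs(back[[1]] - vid[[1]])), 1 / 255)
  unlink(d, recursive = TRUE)
})
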