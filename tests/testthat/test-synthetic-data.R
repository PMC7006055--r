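test_that("jaw trace generator produces the requested cycle structure", {
  g <- gen_jaw_trace(jaw_trace_spec(lick_rate_hz = 8, duration_s = 2,
                                    fps = 30, noise_sd_mm = 0, seed = 1))
  expect_length(g$truth$cycle_max_times, 16)
  expect_length(g$truth$cycle_min_times, 16)
  expect_equal(mean(diff(g$truth$cycle_min_times)) * 1000, 125)
  expect_equal(length(g$trace), 60)
  expect_true(all(g$trace$values >= 0.5 - 1e-12))

  # realistic wild-type lick rate is accepted and gives ~17 cycles in 2 s
  g2 <- gen_jaw_trace(jaw_trace_spec(lick_rate_hz = 8.71, duration_s = 2))
  expect_length(g2$truth$cycle_max_times, 17)
})

test_that("jaw trace generator is deterministic given spec and seed", {
  sp <- jaw_trace_spec(noise_sd_mm = 0.2, seed = 42)
  expect_identical(gen_jaw_trace(sp)$trace$values,
                   gen_jaw_trace(sp)$trace$values)
  sp2 <- jaw_trace_spec(noise_sd_mm = 0.2, seed = 43)
  expect_false(identical(gen_jaw_trace(sp)$trace$values,
                         gen_jaw_trace(sp2)$trace$values))
})

test_that("jaw trace spec rejects invalid parameters", {
  expect_error(jaw_trace_spec(lick_rate_hz = 0), "lick_rate_hz")
  expect_error(jaw_trace_spec(duration_s = -1), "duration_s")
  expect_error(jaw_trace_spec(lick_rate_hz = 8, fps = 10), "fps")
  expect_error(jaw_trace_spec(noise_sd_mm = -0.1), "noise_sd")
})

test_that("swallow annotations land on cycle minima with the stated transit", {
  g <- gen_jaw_trace(jaw_trace_spec(lick_rate_hz = 8, duration_s = 4, fps = 30,
                                    swallow_every_n_licks = 4, ptt_frames = 3))
  sw <- g$truth$swallows
  expect_equal(sw$esophagus_entry_frame - sw$rest_frame,
               rep(3L, nrow(sw)))
  # rest frames sit at every 4th cycle-closing minimum (0.5 s apart at 8 Hz)
  expect_equal(diff(sw$rest_frame), rep(15L, nrow(sw) - 1))
})

test_that("glottal generator encodes normal vs paradoxical motion", {
  gn <- gen_glottal_traces(glottal_trace_spec(respiratory_rate_per_min = 150,
                                              duration_s = 10, noise_sd_px = 0))
  expect_length(gn$truth$cycle_max_times, 25)
  expect_equal(cor(diff(gn$left$values), diff(gn$right$values)), -1)

  gp <- gen_glottal_traces(glottal_trace_spec(paradoxical = TRUE))
  expect_equal(cor(diff(gp$left$values), diff(gp$right$values)), 1)

  # amplitude asymmetry is exact by construction
  ga <- gen_glottal_traces(glottal_trace_spec(left_amplitude_px = 10,
                                              right_amplitude_px = 5))
  al <- diff(range(ga$left$values))
  ar <- diff(range(ga$right$values))
  expect_equal(min(al, ar) / max(al, ar), 0.5, tolerance = 1e-3)
})

test_that("histology generator paints the requested pool fraction exactly", {
  h0 <- gen_histology_image(histology_image_spec(pool_area_fraction = 0))
  expect_equal(h0$truth$true_inflamed_fraction, 0)
  expect_false(any(h0$truth$pool_mask))

  h <- gen_histology_image(histology_image_spec(pool_area_fraction = 0.05,
                                                seed = 11))
  # brute-force pixel count of the painted pool color
  img <- h$image
  pool <- h$truth$parameters$pool_color
  painted <- img[, , 1] == pool[1] & img[, , 2] == pool[2] & img[, , 3] == pool[3]
  expect_equal(sum(painted) / prod(dim(img)[1:2]), 0.05, tolerance = 1e-4)
  expect_equal(h$truth$true_inflamed_fraction,
               sum(painted) / prod(dim(img)[1:2]))

  sp <- histology_image_spec(pool_area_fraction = 0.1, seed = 9)
  expect_identical(gen_histology_image(sp)$image, gen_histology_image(sp)$image)
  expect_error(histology_image_spec(pool_area_fraction = 0.6), "0.5")
  expect_error(histology_image_spec(pool_color = c(1, 1, 1)), "darker")
})

test_that("home-cage log generator respects rates, ordering and non-overlap", {
  empty <- gen_homecage_log(behavior_log_spec(rates_per_hour = c(drinking = 0),
                                              mean_event_duration_s = c(drinking = 1)))
  expect_equal(nrow(empty$log), 0)

  # single-class Poisson count recovery: 3.43/h over 72 h, mean 246.96
  counts <- vapply(1:20, function(s) {
    nrow(gen_homecage_log(behavior_log_spec(
      rates_per_hour = c(drinking = 3.43),
      mean_event_duration_s = c(drinking = 1.3),
      total_hours = 72, seed = s))$log)
  }, numeric(1))
  lambda <- 3.43 * 72
  expect_true(abs(mean(counts) - lambda) < 3 * sqrt(lambda))

  # invariants for arbitrary seeds: sorted, non-overlapping, inside recording
  for (s in c(1, 7, 99)) {
    hl <- gen_homecage_log(behavior_log_spec(seed = s))
    expect_silent(check_behavior_log(hl$log, total_hours = 72))
    expect_false(is.unsorted(hl$log$start_s))
  }

  expect_error(behavior_log_spec(rates_per_hour = c(g = 200),
                                 mean_event_duration_s = c(g = 60)),
               "overlap")
})

test_that("rendered marker videos match truth geometry", {
  n <- 5
  truth <- list(positions = list(
    a = cbind(x = rep(50, n), y = rep(50, n)),
    b = cbind(x = rep(50, n), y = rep(100, n))))
  vid <- render_marker_video(truth, list(width_px = 128, height_px = 128,
                                         bar_length_px = 100))
  # brightest-blob centroids at the stated coordinates in every frame
  for (fi in 2:n) {  # frame 0 also carries the calibration bar
    img <- vid[[fi]]
    bright <- which(img > 0.9, arr.ind = TRUE)
    ys <- bright[, 1] - 1; xs <- bright[, 2] - 1
    expect_equal(as.numeric(sort(round(tapply(ys, ys > 75, mean)))), c(50, 100))
    expect_equal(round(mean(xs)), 50)
  }
  # calibration bar in frame 0: 100 bright pixels in one row away from markers
  bar <- vid[[1]][3, ] == 1
  expect_equal(sum(bar), 100)
  expect_error(render_marker_video(list(positions = list(
    a = cbind(x = 127, y = 5))), list(width_px = 128, height_px = 128)),
    "outside frame")
})

test_that("trace and log CSV round-trips preserve the data", {
  tr <- motion_trace(sin(1:50), fps = 30, units = "mm")
  f <- tempfile(fileext = ".csv")
  write_motion_trace(tr, f)
  tr2 <- read_motion_trace(f)
  expect_equal(tr2$values, tr$values)
  expect_equal(tr2$fps, 30)

  hl <- gen_homecage_log(behavior_log_spec(seed = 2))
  f2 <- tempfile(fileext = ".csv")
  write_behavior_log(hl$log, f2)
  expect_equal(read_behavior_log(f2)$start_s, hl$log$start_s)
  unlink(c(f, f2))
})
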