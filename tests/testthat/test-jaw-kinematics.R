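test_that("clip splicing follows the swallow-aligned window convention", {
  tr <- motion_trace(rep(1, 300), fps = 30, units = "mm")
  sp <- splice_clip(tr, swallow_frame = 100, clip_seconds = 2)
  expect_equal(sp$window_frames, c(100, 159))
  expect_equal(sp$clip_start_frame, 95)
  expect_equal(length(sp$clip), 70)  # 60-frame window + 5 context each end
  expect_equal(sp$window_time, c(100, 160) / 30)

  # left context clamps at the start of the trace
  sp2 <- splice_clip(tr, swallow_frame = 2, clip_seconds = 2)
  expect_equal(sp2$clip_start_frame, 0)
  expect_equal(sp2$window_frames, c(2, 61))

  # 20 s eating window at 30 fps covers 600 frames
  tr20 <- motion_trace(rep(1, 650), fps = 30, units = "mm")
  sp3 <- splice_clip(tr20, swallow_frame = 10, clip_seconds = 20)
  expect_equal(diff(sp3$window_frames) + 1, 600)

  expect_error(splice_clip(tr, swallow_frame = 400), "outside")
  expect_error(splice_clip(tr, swallow_frame = 290, clip_seconds = 2), "past the end")
})

test_that("cycle detection matches analytic truth on clean and noisy traces", {
  g <- gen_jaw_trace(jaw_trace_spec(lick_rate_hz = 8, duration_s = 2, fps = 30))
  ev <- detect_jaw_cycles(g$trace)
  expect_length(ev$open_times, 16)
  expect_length(ev$close_times, 16)
  expect_lt(max(abs(ev$open_times - g$truth$cycle_max_times)), 1 / 30 + 1e-9)
  expect_lt(max(abs(ev$close_times - g$truth$cycle_min_times)), 1 / 30 + 1e-9)

  # 5% amplitude noise: event times still within one frame of truth
  gn <- gen_jaw_trace(jaw_trace_spec(lick_rate_hz = 6, amplitude_mm = 3,
                                     duration_s = 2, fps = 60,
                                     noise_sd_mm = 0.15, seed = 8))
  evn <- detect_jaw_cycles(gn$trace)
  expect_equal(length(evn$open_times), length(gn$truth$cycle_max_times))
  expect_lt(max(abs(evn$open_times - gn$truth$cycle_max_times)), 1 / 60 + 1e-9)

  # constant trace: zero events, not an error
  flat <- detect_jaw_cycles(motion_trace(rep(2, 100), fps = 30, units = "mm"))
  expect_length(flat$open_times, 0)
  expect_length(flat$close_times, 0)
})

test_that("detected events can be manually reviewed and edited", {
  g <- gen_jaw_trace(jaw_trace_spec(lick_rate_hz = 8, duration_s = 2))
  ev <- detect_jaw_cycles(g$trace)
  ev2 <- suppressWarnings(remove_cycle_event(ev, "open", ev$open_times[1]))
  expect_length(ev2$open_times, 15)
  ev3 <- suppressWarnings(add_cycle_event(ev2, "open", g$truth$cycle_max_times[1]))
  expect_length(ev3$open_times, 16)
  expect_error(remove_cycle_event(ev, "close", 99), "no close event")
})

test_that("drinking metrics are exact on an analytically forced configuration", {
  # uniform 8 Hz train, swallows every 500 ms, 3-frame transit at 30 fps
  g <- gen_jaw_trace(jaw_trace_spec(lick_rate_hz = 8, duration_s = 4, fps = 30,
                                    swallow_every_n_licks = 4, ptt_frames = 3))
  ev <- cycle_events(g$truth$cycle_max_times, g$truth$cycle_min_times)
  sp <- splice_clip(g$trace, g$truth$swallows$swallow_frame[1], clip_seconds = 2)
  dm <- compute_drinking_metrics(ev, g$truth$swallows, g$trace, sp$window_time)
  expect_equal(dm$lick_rate, 8)
  expect_equal(dm$inter_lick_interval, 125)
  expect_equal(dm$swallow_rate, 2)
  expect_equal(dm$inter_swallow_interval, 500)
  expect_equal(dm$lick_swallow_ratio, 4)
  expect_equal(dm$pharyngeal_transit_time, 100)
})

test_that("phase velocity equals excursion over phase duration", {
  # triangle wave: opens 5 mm in 62.5 ms -> 80 mm/s
  fps <- 32
  vals <- rep(c(0, 2.5, 5, 2.5), 9)[1:33]   # 2 frames up = 62.5 ms
  tr <- motion_trace(vals, fps = fps, units = "mm")
  ev <- detect_jaw_cycles(tr, min_prominence_mm = 1)
  dm <- suppressWarnings(compute_drinking_metrics(ev, NULL, tr, c(0, 1)))
  expect_equal(dm$jaw_opening_velocity, 80)
  expect_equal(dm$jaw_closing_velocity, 80)
})

test_that("metrics needing swallows are missing, not zero, without them", {
  g <- gen_jaw_trace(jaw_trace_spec(lick_rate_hz = 8, duration_s = 3))
  ev <- cycle_events(g$truth$cycle_max_times, g$truth$cycle_min_times)
  expect_warning(
    dm <- compute_drinking_metrics(ev, NULL, g$trace, c(0.5, 2.5)),
    "missing")
  expect_true(is.na(dm$inter_swallow_interval))
  expect_true(is.na(dm$lick_swallow_ratio))
  expect_true(is.na(dm$pharyngeal_transit_time))
  expect_equal(dm$swallow_rate, 0)
  expect_false(is.na(dm$lick_rate))
})

test_that("eating metrics follow the rotary-episode averaging rule", {
  # closes every 1/8 s in [2,3), every 1/8 s in [5,6), 9 cycles in [8,9)
  closes <- c(2 + (0:7) / 8, 5 + (0:7) / 8, 8 + (0:8) / 9)
  opens <- closes + 0.05
  ev <- suppressWarnings(cycle_events(opens, closes))
  tr <- motion_trace(rep(1, 20 * 30), fps = 30, units = "mm")
  rot <- data.frame(start_s = c(2, 5, 8), end_s = c(3, 6, 9))
  swf <- data.frame(rest_frame = c(0, 150, 300, 450),
                    esophagus_entry_frame = c(3, 153, 303, 453),
                    swallow_frame = c(0, 150, 300, 450))
  em <- compute_eating_metrics(ev, swf, rot, tr, c(0, 20))
  expect_equal(em$mastication_rate, mean(c(8, 8, 9)))
  expect_equal(em$swallow_rate, 0.2)
  expect_equal(em$inter_swallow_interval, 5)
  expect_error(compute_eating_metrics(ev, swf, data.frame(start_s = -1, end_s = 0),
                                      tr, c(0, 20)), "outside")
  expect_warning(compute_eating_metrics(ev, swf, rot[1:2, ], tr, c(0, 20)),
                 "fewer than three")
})

test_that("per-mouse aggregation averages clips and propagates missingness", {
  mk <- function(lr, isi = 500) structure(
    list(lick_rate = lr, inter_lick_interval = 120, swallow_rate = 2,
         inter_swallow_interval = isi, lick_swallow_ratio = 4,
         pharyngeal_transit_time = 100, jaw_opening_velocity = 14,
         jaw_closing_velocity = 14), class = "drinking_metrics")
  clips <- lapply(c(8, 8, 8, 9, 9), mk)
  rec <- aggregate_mouse(clips)
  expect_equal(rec$drinking_lick_rate, 8.4)

  # identical clips aggregate to the clip value
  rec1 <- aggregate_mouse(lapply(rep(8, 5), mk))
  expect_equal(rec1$drinking_lick_rate, 8)

  # one missing ISI: mean over the remaining four
  clips2 <- c(lapply(c(8, 8, 8, 9), function(l) mk(l, 500)), list(mk(9, NA)))
  rec2 <- aggregate_mouse(clips2)
  expect_equal(rec2$drinking_inter_swallow_interval, 500)

  expect_error(aggregate_mouse(list()), "at least one")
  df <- as.data.frame(rec)
  expect_equal(nrow(df), 1)
  expect_true("drinking_lick_rate" %in% names(df))
})

test_that("metrics are invariant to added context frames", {
  g <- gen_jaw_trace(jaw_trace_spec(lick_rate_hz = 8, duration_s = 4, fps = 30,
                                    swallow_every_n_licks = 4))
  ev <- cycle_events(g$truth$cycle_max_times, g$truth$cycle_min_times)
  s5 <- splice_clip(g$trace, 30, clip_seconds = 2, context_frames = 5)
  s0 <- splice_clip(g$trace, 30, clip_seconds = 2, context_frames = 0)
  m5 <- compute_drinking_metrics(ev, g$truth$swallows, g$trace, s5$window_time)
  m0 <- compute_drinking_metrics(ev, g$truth$swallows, g$trace, s0$window_time)
  expect_equal(unclass(m5), unclass(m0))
})

test_that("uniform train identity: lick rate times ILI is 1000", {
  for (rate in c(5, 6, 7.5)) {
    g <- gen_jaw_trace(jaw_trace_spec(lick_rate_hz = rate, duration_s = 4,
                                      fps = 30, swallow_every_n_licks = 3))
    ev <- detect_jaw_cycles(g$trace)
    sp <- splice_clip(g$trace, g$truth$swallows$swallow_frame[1], 2)
    dm <- compute_drinking_metrics(ev, g$truth$swallows, g$trace, sp$window_time)
    expect_lt(abs(dm$lick_rate * dm$inter_lick_interval - 1000),
              1000 / 30 * dm$lick_rate)
    # PTT is an integer multiple of the frame period
    frames <- dm$pharyngeal_transit_time * 30 / 1000
    expect_equal(frames, round(frames))
  }
})
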