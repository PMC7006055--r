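#' Specification of a synthetic jaw-gape (licking) trace
#'
#' Parameters of a raised-cosine licking waveform with optional embedded
#' swallow events. The gape signal is
#' \deqn{g(t) = baseline + (A/2)\,(1 - \cos 2\pi f t)}
#' so every cycle has a well-defined "closed" minimum (the lick event used
#' to timestamp cycles) and "open" maximum. Defaults follow typical adult
#' wild-type mouse drinking kinematics: lick rate 8.71 cycles/s recorded at
#' 30 fps.
#'
#' @param lick_rate_hz Lick (jaw open/close) cycles per second, > 0.
#' @param amplitude_mm Peak-to-trough gape excursion in mm.
#' @param baseline_mm Minimum gape (jaw closed) in mm.
#' @param duration_s Trace length in seconds, > 0.
#' @param fps Sampling rate, frames/s; must be at least `2 * lick_rate_hz`.
#' @param noise_sd_mm SD of additive Gaussian noise, >= 0.
#' @param swallow_every_n_licks Place a synthetic swallow at every n-th cycle
#'   minimum, or `NULL` for no swallows.
#' @param ptt_frames Bolus pharyngeal transit length per swallow, in frames
#'   (esophagus-entry frame = rest frame + `ptt_frames`).
#' @param seed Integer seed; same spec + seed gives bit-identical output.
#' @return A `jaw_trace_spec` list, validated.
#' @export
jaw_trace_spec <- function(lick_rate_hz = 8.71,
                           amplitude_mm = 3,
                           baseline_mm = 0.5,
                           duration_s = 2,
                           fps = 30,
                           noise_sd_mm = 0,
                           swallow_every_n_licks = NULL,
                           ptt_frames = 3L,
                           seed = 1L) {
  if (lick_rate_hz <= 0) stop("lick_rate_hz must be > 0", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (fps < 2 * lick_rate_hz) {
    stop("fps must be at least twice lick_rate_hz (sampling theorem)",
         call. = FALSE)
  }
  if (noise_sd_mm < 0) stop("noise_sd_mm must be >= 0", call. = FALSE)
  if (!is.null(swallow_every_n_licks)) {
    swallow_every_n_licks <- as.integer(swallow_every_n_licks)
    if (swallow_every_n_licks < 1L) {
      stop("swallow_every_n_licks must be a positive integer or NULL",
           call. = FALSE)
    }
  }
  structure(list(lick_rate_hz = lick_rate_hz, amplitude_mm = amplitude_mm,
                 baseline_mm = baseline_mm, duration_s = duration_s,
                 fps = fps, noise_sd_mm = noise_sd_mm,
                 swallow_every_n_licks = swallow_every_n_licks,
                 ptt_frames = as.integer(ptt_frames), seed = seed),
            class = "jaw_trace_spec")
}

#' Generate a synthetic jaw-gape trace with known ground truth
#'
#' Samples the raised-cosine licking waveform of [jaw_trace_spec()] on the
#' frame grid `t = 0, 1/fps, ..., (n-1)/fps` with `n = floor(duration * fps)`
#' frames, so a noise-free trace contains exactly `floor(duration *
#' lick_rate_hz)` complete open/close cycles. The truth records analytic
#' extremum times, swallow annotations, and per-frame 2D positions of an
#' upper (fixed) and lower (moving) jaw marker so the trace can also be
#' rendered to video and re-tracked.
#'
#' @param spec A [jaw_trace_spec()].
#' @return List with elements `trace` (a [motion_trace()] in mm) and `truth`:
#'   \describe{
#'     \item{cycle_max_times}{analytic gape-maximum times (jaw open), s}
#'     \item{cycle_min_times}{analytic gape-minimum times (jaw closed), s}
#'     \item{swallows}{data.frame `rest_frame`, `esophagus_entry_frame`,
#'       `swallow_frame` (0-based) or NULL}
#'     \item{positions}{list of n x 2 matrices (`upper_jaw`, `lower_jaw`),
#'       px, origin top-left, x right, y down}
#'     \item{mm_per_pixel, bar_length_px}{geometry used for the marker
#'       positions and the 10 mm calibration bar}
#'     \item{parameters}{echo of `spec`}
#'   }
#' @examples
#' g <- gen_jaw_trace(jaw_trace_spec(lick_rate_hz = 8, duration_s = 2, seed = 7))
#' length(g$truth$cycle_max_times)  # 16 cycles
#' @export
gen_jaw_trace <- function(spec) {
  stopifnot(inherits(spec, "jaw_trace_spec"))
  f <- spec$lick_rate_hz
  n <- floor(spec$duration_s * spec$fps)
  if (n < 3L) stop("duration too short for the given fps", call. = FALSE)
  t <- (seq_len(n) - 1) / spec$fps
  gape <- spec$baseline_mm + (spec$amplitude_mm / 2) * (1 - cos(2 * pi * f * t))
  if (spec$noise_sd_mm > 0) {
    gape <- gape + with_seed(spec$seed, stats::rnorm(n, 0, spec$noise_sd_mm))
  }

  n_cycles <- floor(spec$duration_s * f)
  max_times <- (seq_len(n_cycles) - 0.5) / f
  min_times <- (seq_len(n_cycles) - 1) / f  # includes t = 0 (start closed)

  swallows <- NULL
  if (!is.null(spec$swallow_every_n_licks)) {
    m <- spec$swallow_every_n_licks
    ks <- seq(m, n_cycles, by = m)
    rest <- round(ks / f * spec$fps)       # cycle-closing minima, frame index
    entry <- rest + spec$ptt_frames
    keep <- entry <= n - 1L
    if (any(keep)) {
      swallows <- data.frame(rest_frame = as.integer(rest[keep]),
                             esophagus_entry_frame = as.integer(entry[keep]),
                             swallow_frame = as.integer(rest[keep]))
    }
  }

  # marker geometry for rendering / tracking round-trips
  mm_per_pixel <- 0.1
  upper <- cbind(x = rep(64, n), y = rep(20, n))
  lower <- cbind(x = rep(64, n), y = 20 + gape / mm_per_pixel)

  list(trace = motion_trace(gape, fps = spec$fps, units = "mm"),
       truth = list(cycle_max_times = max_times,
                    cycle_min_times = min_times,
                    swallows = swallows,
                    positions = list(upper_jaw = upper, lower_jaw = lower),
                    mm_per_pixel = mm_per_pixel,
                    bar_length_px = 100,
                    parameters = spec))
}

#' Specification of synthetic left/right glottal motion traces
#'
#' Emulates the oscillatory abduction/adduction of the left and right glottal
#' edges during spontaneous breathing, viewed endoscopically. Each side's
#' lateral excursion from a resting half-width is a raised cosine at the
#' respiratory frequency; in normal motion the two sides move in opposite
#' image directions (anti-phase, velocity correlation -1), in paradoxical
#' motion in the same direction (+1). Default rate 150 cycles/min is in the
#' normal murine range under light anesthesia.
#'
#' @param respiratory_rate_per_min Respiratory cycles per minute, > 0.
#' @param left_amplitude_px,right_amplitude_px Lateral excursion amplitude of
#'   each side, px, >= 0.
#' @param halfwidth_px Resting half glottal width (adducted), px.
#' @param marker_height_px Vertical offset of the glottal-edge markers above
#'   the dorsal commissure, px.
#' @param paradoxical If `TRUE`, both sides move in the same direction.
#' @param noise_sd_px SD of additive Gaussian noise, px.
#' @param duration_s Clip length, s (default 10, the standard analysis clip).
#' @param fps Frames per second.
#' @param seed Integer seed.
#' @return A `glottal_trace_spec` list, validated.
#' @export
glottal_trace_spec <- function(respiratory_rate_per_min = 150,
                               left_amplitude_px = 10,
                               right_amplitude_px = 10,
                               halfwidth_px = 8,
                               marker_height_px = 40,
                               paradoxical = FALSE,
                               noise_sd_px = 0,
                               duration_s = 10,
                               fps = 30,
                               seed = 1L) {
  if (respiratory_rate_per_min <= 0) {
    stop("respiratory_rate_per_min must be > 0", call. = FALSE)
  }
  if (left_amplitude_px < 0 || right_amplitude_px < 0) {
    stop("amplitudes must be >= 0", call. = FALSE)
  }
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (noise_sd_px < 0) stop("noise_sd_px must be >= 0", call. = FALSE)
  f <- respiratory_rate_per_min / 60
  if (fps < 2 * f) stop("fps must be at least twice the respiratory frequency",
                        call. = FALSE)
  structure(list(respiratory_rate_per_min = respiratory_rate_per_min,
                 left_amplitude_px = left_amplitude_px,
                 right_amplitude_px = right_amplitude_px,
                 halfwidth_px = halfwidth_px,
                 marker_height_px = marker_height_px,
                 paradoxical = isTRUE(paradoxical),
                 noise_sd_px = noise_sd_px,
                 duration_s = duration_s, fps = fps, seed = seed),
            class = "glottal_trace_spec")
}

#' Generate synthetic glottal motion traces with known ground truth
#'
#' Lateral coordinates are signed distances from the glottal midline on the
#' shared image x axis: left negative, right positive. At `t = 0` the glottis
#' is maximally adducted (expiration); abduction maxima fall at the cycle
#' midpoints. Truth carries per-frame 2D positions of the left/right glottal
#' edge markers and the (static) dorsal commissure for rendering and
#' re-tracking.
#'
#' @param spec A [glottal_trace_spec()].
#' @return List with `left`, `right` (lateral-coordinate [motion_trace()]s in
#'   px) and `truth` (cycle times, per-frame `positions` for `left_glottal`,
#'   `right_glottal`, `dorsal_commissure`, and the echoed `parameters`).
#' @examples
#' g <- gen_glottal_traces(glottal_trace_spec(respiratory_rate_per_min = 150))
#' length(g$truth$cycle_max_times)  # 25 cycles in 10 s
#' @export
gen_glottal_traces <- function(spec) {
  stopifnot(inherits(spec, "glottal_trace_spec"))
  f <- spec$respiratory_rate_per_min / 60
  n <- floor(spec$duration_s * spec$fps)
  t <- (seq_len(n) - 1) / spec$fps
  exc_l <- (spec$left_amplitude_px / 2) * (1 - cos(2 * pi * f * t))
  exc_r <- (spec$right_amplitude_px / 2) * (1 - cos(2 * pi * f * t))
  if (spec$paradoxical) {
    # both edges displace in the +x image direction
    xl <- -spec$halfwidth_px + exc_l
  } else {
    xl <- -spec$halfwidth_px - exc_l
  }
  xr <- spec$halfwidth_px + exc_r
  if (spec$noise_sd_px > 0) {
    noise <- with_seed(spec$seed, matrix(stats::rnorm(2 * n, 0, spec$noise_sd_px), ncol = 2))
    xl <- xl + noise[, 1]
    xr <- xr + noise[, 2]
  }

  n_cycles <- floor(spec$duration_s * f)
  cx <- 64; cy <- 100
  truth <- list(
    cycle_max_times = (seq_len(n_cycles) - 0.5) / f,  # max abduction
    cycle_min_times = (seq_len(n_cycles) - 1) / f,    # max adduction
    positions = list(
      left_glottal = cbind(x = cx + xl, y = rep(cy - spec$marker_height_px, n)),
      right_glottal = cbind(x = cx + xr, y = rep(cy - spec$marker_height_px, n)),
      dorsal_commissure = cbind(x = rep(cx, n), y = rep(cy, n))),
    parameters = spec)

  list(left = motion_trace(xl, fps = spec$fps, units = "px"),
       right = motion_trace(xr, fps = spec$fps, units = "px"),
       truth = truth)
}

#' Render ground-truth marker positions into a synthetic video
#'
#' Produces grayscale frames (matrices in \[0, 1\], indexed `[row, col]` =
#' `[y + 1, x + 1]` for 0-based pixel coordinates) containing one
#' anti-aliased bright disk per marker on a dark background, plus a
#' horizontal calibration bar of known pixel length (representing 10 mm)
#' drawn in frame 0 only, emulating the calibration marker at the top of a
#' fluoroscopic recording.
#'
#' @param truth A `truth` list from [gen_jaw_trace()] or
#'   [gen_glottal_traces()] (must contain per-frame `positions`).
#' @param geometry List: `width_px`, `height_px` (frame size),
#'   `marker_radius_px` (default 3), `bar_length_px` (default
#'   `truth$bar_length_px` or 100), `bar_row`, `bar_col` (top-left of the
#'   bar, 0-based, defaults 2, 10).
#' @return List of `height_px` x `width_px` numeric matrices, one per frame.
#' @export
render_marker_video <- function(truth, geometry = list()) {
  pos <- truth$positions
  if (is.null(pos)) stop("truth has no per-frame marker positions", call. = FALSE)
  w <- geometry$width_px %||% 128L
  h <- geometry$height_px %||% 128L
  r <- geometry$marker_radius_px %||% 3
  bar_len <- geometry$bar_length_px %||% truth$bar_length_px %||% 100
  bar_row <- geometry$bar_row %||% 2L
  bar_col <- geometry$bar_col %||% 10L
  n <- nrow(pos[[1]])
  for (p in pos) {
    if (any(p[, 1] < r | p[, 1] > w - 1 - r | p[, 2] < r | p[, 2] > h - 1 - r)) {
      stop("marker position outside frame bounds", call. = FALSE)
    }
  }
  if (bar_col + bar_len > w) stop("calibration bar does not fit in frame", call. = FALSE)

  bg <- 0.08
  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)   # x of each pixel
  ys <- matrix(rep(0:(h - 1), times = w), nrow = h)  # y of each pixel
  frames <- vector("list", n)
  for (fi in seq_len(n)) {
    img <- matrix(bg, nrow = h, ncol = w)
    for (p in pos) {
      d <- sqrt((xs - p[fi, 1])^2 + (ys - p[fi, 2])^2)
      cov <- pmin(pmax(r + 0.5 - d, 0), 1)  # anti-aliased disk edge
      img <- pmax(img, bg + (1 - bg) * cov)
    }
    if (fi == 1L) {
      img[bar_row + 1L, (bar_col + 1L):(bar_col + bar_len)] <- 1
    }
    frames[[fi]] <- img
  }
  frames
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specification of a synthetic H&E-like histology image
#'
#' Emulates an H&E-stained lung section: pink tissue on a white slide
#' background, with a known number of dark red/purple "erythrocyte pool"
#' regions painted to an exact target pixel fraction of the whole image.
#'
#' @param width_px,height_px Image size.
#' @param pool_area_fraction Target inflamed fraction of *total* image
#'   pixels, in \[0, 0.5\].
#' @param pool_count Number of pool regions.
#' @param tissue_color,pool_color,background_color RGB triples in \[0, 1\];
#'   the pool must be darker (lower luminance) than the tissue.
#' @param background_margin_px Width of the white background border framing
#'   the tissue.
#' @param seed Integer seed.
#' @return A `histology_image_spec` list, validated.
#' @export
histology_image_spec <- function(width_px = 200L, height_px = 200L,
                                 pool_area_fraction = 0.05,
                                 pool_count = 3L,
                                 tissue_color = c(0.96, 0.75, 0.80),
                                 pool_color = c(0.45, 0.10, 0.25),
                                 background_color = c(1, 1, 1),
                                 background_margin_px = 10L,
                                 seed = 1L) {
  if (pool_area_fraction < 0 || pool_area_fraction > 0.5) {
    stop("pool_area_fraction must be in [0, 0.5]", call. = FALSE)
  }
  lum <- function(rgb) sum(c(0.299, 0.587, 0.114) * rgb)
  if (lum(pool_color) >= lum(tissue_color)) {
    stop("pool_color must be darker (lower luminance) than tissue_color",
         call. = FALSE)
  }
  if (pool_count < 1L) stop("pool_count must be >= 1", call. = FALSE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pool_area_fraction = pool_area_fraction,
                 pool_count = as.integer(pool_count),
                 tissue_color = tissue_color, pool_color = pool_color,
                 background_color = background_color,
                 background_margin_px = as.integer(background_margin_px),
                 seed = seed),
            class = "histology_image_spec")
}

#' Generate a synthetic histology image with known inflamed fraction
#'
#' Pools are quasi-circular: for each pool, exactly the target number of
#' pixels nearest its center are painted, so the ground-truth inflamed
#' fraction equals the requested fraction up to integer rounding. Pool
#' centers are placed by rejection sampling with clearance from the
#' background border and from each other; an error is raised if the
#' requested pools cannot fit.
#'
#' @param spec A [histology_image_spec()].
#' @return List with `image` (h x w x 3 array in \[0, 1\]) and `truth`
#'   (`pool_mask` logical matrix, `background_mask`,
#'   `true_inflamed_fraction`, `parameters`).
#' @export
gen_histology_image <- function(spec) {
  stopifnot(inherits(spec, "histology_image_spec"))
  w <- spec$width_px; h <- spec$height_px; m <- spec$background_margin_px
  total <- w * h
  target <- round(spec$pool_area_fraction * total)
  per_pool <- diff(round(seq(0, target, length.out = spec$pool_count + 1)))

  tissue_x <- c(m, w - 1 - m)  # 0-based tissue bounds, inclusive
  tissue_y <- c(m, h - 1 - m)

  xs <- matrix(rep(0:(w - 1), each = h), nrow = h)
  ys <- matrix(rep(0:(h - 1), times = w), nrow = h)
  pool_mask <- matrix(FALSE, h, w)

  centers <- with_seed(spec$seed, {
    radii <- ceiling(sqrt(per_pool / pi)) + 1
    out <- matrix(NA_real_, spec$pool_count, 2)
    for (i in seq_len(spec$pool_count)) {
      if (per_pool[i] == 0) next
      placed <- FALSE
      for (try in 1:2000) {
        cxy <- c(stats::runif(1, tissue_x[1] + radii[i], tissue_x[2] - radii[i]),
                 stats::runif(1, tissue_y[1] + radii[i], tissue_y[2] - radii[i]))
        if (cxy[1] < tissue_x[1] + radii[i] || cxy[2] < tissue_y[1] + radii[i]) next
        ok <- TRUE
        if (i > 1L) {
          for (j in seq_len(i - 1L)) {
            if (!is.na(out[j, 1]) &&
                sqrt(sum((cxy - out[j, ])^2)) < radii[i] + radii[j] + 2) {
              ok <- FALSE
              break
            }
          }
        }
        if (ok) { out[i, ] <- cxy; placed <- TRUE; break }
      }
      if (!placed) stop("requested pools cannot fit in the tissue region",
                        call. = FALSE)
    }
    out
  })

  for (i in seq_len(spec$pool_count)) {
    if (per_pool[i] == 0 || is.na(centers[i, 1])) next
    d <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2
    d[pool_mask] <- Inf  # do not re-paint pixels of an earlier pool
    ord <- order(d)[seq_len(per_pool[i])]
    pool_mask[ord] <- TRUE
  }

  background_mask <- xs < tissue_x[1] | xs > tissue_x[2] |
    ys < tissue_y[1] | ys > tissue_y[2]
  pool_mask[background_mask] <- FALSE

  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(spec$tissue_color[ch], h, w)
    plane[background_mask] <- spec$background_color[ch]
    plane[pool_mask] <- spec$pool_color[ch]
    img[, , ch] <- plane
  }

  list(image = img,
       truth = list(pool_mask = pool_mask,
                    background_mask = background_mask,
                    true_inflamed_fraction = sum(pool_mask) / total,
                    parameters = spec))
}

#' Specification of a synthetic home-cage behavior log
#'
#' Events of each behavior class arrive as a Poisson process at the given
#' hourly rate with exponentially distributed durations; events of one animal
#' are made non-overlapping by thinning (an event starting before the
#' previous one ends is dropped). Defaults are realistic wild-type values
#' over a 72 h recording: drinking 3.43/h, eating 19/h, grooming 16.11/h.
#'
#' @param rates_per_hour Named numeric vector, mean events/hour per class.
#' @param mean_event_duration_s Named numeric vector, mean event duration per
#'   class (seconds); names must match `rates_per_hour`.
#' @param total_hours Recording length in hours (default 72).
#' @param seed Integer seed.
#' @return A `behavior_log_spec` list, validated.
#' @export
behavior_log_spec <- function(rates_per_hour = c(drinking = 3.43,
                                                 eating = 19.0,
                                                 grooming = 16.11),
                              mean_event_duration_s = c(drinking = 1.30,
                                                        eating = 0.97,
                                                        grooming = 31.47),
                              total_hours = 72,
                              seed = 1L) {
  if (any(rates_per_hour < 0)) stop("rates must be >= 0", call. = FALSE)
  if (total_hours <= 0) stop("total_hours must be > 0", call. = FALSE)
  if (!setequal(names(rates_per_hour), names(mean_event_duration_s))) {
    stop("rates_per_hour and mean_event_duration_s must share class names",
         call. = FALSE)
  }
  if (any(mean_event_duration_s <= 0)) {
    stop("mean_event_duration_s must be > 0", call. = FALSE)
  }
  # occupancy check: overlap rejection must stay a rare event
  busy <- sum(rates_per_hour * mean_event_duration_s[names(rates_per_hour)]) / 3600
  if (busy > 0.5) {
    stop("rates too high: expected cage occupancy exceeds 50%, events could ",
         "not avoid overlap", call. = FALSE)
  }
  structure(list(rates_per_hour = rates_per_hour,
                 mean_event_duration_s = mean_event_duration_s,
                 total_hours = total_hours, seed = seed),
            class = "behavior_log_spec")
}

#' Generate a synthetic home-cage behavior event log
#'
#' @param spec A [behavior_log_spec()].
#' @return List with `log` (data.frame `class`, `start_s`, `duration_s`,
#'   sorted, non-overlapping, all within the recording) and `truth`
#'   (`event_times` per class after thinning, `parameters`).
#' @export
gen_homecage_log <- function(spec) {
  stopifnot(inherits(spec, "behavior_log_spec"))
  total_s <- spec$total_hours * 3600
  log <- with_seed(spec$seed, {
    rows <- list()
    for (cls in names(spec$rates_per_hour)) {
      rate <- spec$rates_per_hour[[cls]]
      if (rate == 0) next
      nev <- stats::rpois(1, rate * spec$total_hours)
      if (nev == 0) next
      starts <- sort(stats::runif(nev, 0, total_s))
      durs <- stats::rexp(nev, 1 / spec$mean_event_duration_s[[cls]])
      rows[[cls]] <- data.frame(class = cls, start_s = starts, duration_s = durs)
    }
    if (length(rows) == 0) {
      data.frame(class = character(), start_s = numeric(), duration_s = numeric())
    } else {
      df <- do.call(rbind, rows)
      df <- df[order(df$start_s), , drop = FALSE]
      # thin overlaps: drop events starting before the previous kept one ends
      keep <- logical(nrow(df))
      prev_end <- -Inf
      for (i in seq_len(nrow(df))) {
        if (df$start_s[i] >= prev_end) {
          keep[i] <- TRUE
          prev_end <- df$start_s[i] + df$duration_s[i]
        }
      }
      df <- df[keep, , drop = FALSE]
      # truncate anything running past the end of the recording
      df$duration_s <- pmin(df$duration_s, total_s - df$start_s)
      rownames(df) <- NULL
      df
    }
  })
  event_times <- split(log$start_s, factor(log$class, levels = names(spec$rates_per_hour)))
  list(log = log,
       truth = list(event_times = event_times, parameters = spec))
}

#' Write / read a behavior event log as CSV
#'
#' Columns `class`, `start_s`, `duration_s`, emulating a home-cage monitoring
#' export.
#'
#' @param log Data.frame as produced by [gen_homecage_log()].
#' @param path File path.
#' @return `write_behavior_log` returns `path` invisibly; `read_behavior_log`
#'   returns the data.frame.
#' @export
write_behavior_log <- function(log, path) {
  stopifnot(all(c("class", "start_s", "duration_s") %in% names(log)))
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_log
#' @export
read_behavior_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "start_s", "duration_s") %in% names(df)))
  df
}
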