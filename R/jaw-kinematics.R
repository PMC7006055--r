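#' Ordered jaw open/close cycle events
#'
#' Holds the timestamps (and gape values) of detected gape maxima ("open")
#' and minima ("closed"). A lick cycle is timestamped by its closing
#' minimum, which marks completion of the lick.
#'
#' @param open_times,close_times Strictly increasing timestamps (s) of gape
#'   maxima and minima.
#' @param open_values,close_values Optional gape values at those events.
#' @return A `cycle_events` object.
#' @export
cycle_events <- function(open_times, close_times,
                         open_values = NULL, close_values = NULL) {
  open_times <- as.numeric(open_times); close_times <- as.numeric(close_times)
  if (is.unsorted(open_times, strictly = TRUE) && length(open_times) > 1) {
    stop("open_times must be strictly increasing", call. = FALSE)
  }
  if (is.unsorted(close_times, strictly = TRUE) && length(close_times) > 1) {
    stop("close_times must be strictly increasing", call. = FALSE)
  }
  ev <- structure(list(open_times = open_times, close_times = close_times,
                       open_values = open_values, close_values = close_values),
                  class = "cycle_events")
  if (!events_alternate(ev)) {
    warning("open and close events do not strictly alternate", call. = FALSE)
  }
  ev
}

events_alternate <- function(events) {
  all_t <- c(events$open_times, events$close_times)
  typ <- rep(c(1L, -1L), c(length(events$open_times), length(events$close_times)))
  o <- order(all_t)
  typ <- typ[o]
  length(typ) < 2L || all(diff(typ) != 0L)
}

#' @export
print.cycle_events <- function(x, ...) {
  cat(sprintf("<cycle_events> %d open (max), %d close (min) events\n",
              length(x$open_times), length(x$close_times)))
  invisible(x)
}

#' Manually edit detected cycle events
#'
#' Mirrors the interactive review step of marker-tracking interfaces, where
#' automatically detected open/close events can be added or removed before
#' metrics are computed.
#'
#' @param events A [cycle_events()].
#' @param type `"open"` or `"close"`.
#' @param time Event timestamp (s).
#' @param value Optional gape value at the event.
#' @param tol Matching tolerance in seconds for removal (default 1e-6).
#' @return The edited `cycle_events`.
#' @export
add_cycle_event <- function(events, type = c("open", "close"), time,
                            value = NA_real_) {
  type <- match.arg(type)
  tf <- paste0(type, "_times"); vf <- paste0(type, "_values")
  if (is.null(events[[vf]])) events[[vf]] <- rep(NA_real_, length(events[[tf]]))
  o <- order(c(events[[tf]], time))
  events[[tf]] <- c(events[[tf]], time)[o]
  events[[vf]] <- c(events[[vf]], value)[o]
  cycle_events(events$open_times, events$close_times,
               events$open_values, events$close_values)
}

#' @rdname add_cycle_event
#' @export
remove_cycle_event <- function(events, type = c("open", "close"), time,
                               tol = 1e-6) {
  type <- match.arg(type)
  tf <- paste0(type, "_times"); vf <- paste0(type, "_values")
  hit <- which(abs(events[[tf]] - time) <= tol)
  if (length(hit) == 0) stop("no ", type, " event at time ", time, call. = FALSE)
  events[[tf]] <- events[[tf]][-hit[1]]
  if (!is.null(events[[vf]])) events[[vf]] <- events[[vf]][-hit[1]]
  cycle_events(events$open_times, events$close_times,
               events$open_values, events$close_values)
}

# Alternating extrema of a sampled signal with a prominence floor.
# Returns integer indices and types (+1 max, -1 min). A boundary sample
# counts as an extremum only if its value is within the prominence floor of
# the nearest interior extremum of the same type: analysis clips start at a
# swallow event, which sits at a gape minimum, so the first sample of a
# clip is a genuine "closed" event, whereas a trace cut off mid-phase must
# not contribute a spurious event at its end.
alternating_extrema <- function(v, prominence) {
  n <- length(v)
  if (n < 3L) return(list(idx = integer(0), type = integer(0)))
  keep <- c(TRUE, diff(v) != 0)      # collapse plateau runs to their first sample
  u <- which(keep)
  vu <- v[u]
  m <- length(vu)
  if (m < 2L) return(list(idx = integer(0), type = integer(0)))
  s <- sign(diff(vu))                # all non-zero after collapsing
  typ <- integer(m)
  typ[1] <- -s[1]                    # rising start => boundary minimum
  typ[m] <- s[m - 1]                 # rising end => boundary maximum
  if (m > 2L) {
    interior <- 2:(m - 1)
    change <- s[interior] != s[interior - 1]
    typ[interior][change] <- s[interior - 1][change]
  }
  idx <- u[typ != 0L]
  type <- typ[typ != 0L]

  # boundary acceptance: value must sit at the level of its same-type peers
  boundary_ok <- function(k) {
    same <- setdiff(which(type == type[k]), k)
    if (length(same) == 0L) return(TRUE)
    nearest <- if (k == 1L) same[1] else same[length(same)]
    abs(v[idx[nearest]] - v[idx[k]]) <= prominence
  }
  if (length(idx) >= 2L && idx[length(idx)] == u[m] && !boundary_ok(length(idx))) {
    idx <- idx[-length(idx)]; type <- type[-length(type)]
  }
  if (length(idx) >= 2L && idx[1] == 1L && !boundary_ok(1L)) {
    idx <- idx[-1]; type <- type[-1]
  }

  # prune low-prominence wiggles: repeatedly drop the adjacent extremum pair
  # with the smallest amplitude until all adjacent amplitudes pass the floor
  while (length(idx) >= 2L) {
    amp <- abs(diff(v[idx]))
    k <- which.min(amp)
    if (amp[k] >= prominence) break
    drop <- c(k, k + 1L)
    # merging can leave same-type neighbors; keep the more extreme one
    idx <- idx[-drop]; type <- type[-drop]
    i <- 1L
    while (i < length(idx)) {
      if (type[i] == type[i + 1L]) {
        worse <- if (type[i] > 0) which.min(v[idx[c(i, i + 1L)]]) else which.max(v[idx[c(i, i + 1L)]])
        idx <- idx[-(i + worse - 1L)]; type <- type[-(i + worse - 1L)]
      } else i <- i + 1L
    }
  }
  if (length(idx) == 1L) return(list(idx = integer(0), type = integer(0)))
  list(idx = idx, type = type)
}

#' Detect jaw open/close cycles in a gape trace
#'
#' Finds alternating gape maxima (jaw maximally open) and minima (jaw
#' closed) with a prominence floor, defaulting to 20% of the trace's value
#' range. A constant trace yields zero events (not an error). Detected
#' events can be reviewed and edited with [add_cycle_event()] /
#' [remove_cycle_event()].
#'
#' @param trace A [motion_trace()] (jaw gape, mm).
#' @param min_prominence_mm Minimum peak-to-trough excursion for an event
#'   pair to count; default `0.2 * diff(range(values))`.
#' @return A [cycle_events()] with event times, plus gape values at events.
#' @export
detect_jaw_cycles <- function(trace, min_prominence_mm = NULL) {
  stopifnot(inherits(trace, "motion_trace"))
  v <- trace$values
  if (length(v) < 3L) stop("need at least 3 samples", call. = FALSE)
  rng <- diff(range(v))
  if (is.null(min_prominence_mm)) min_prominence_mm <- 0.2 * rng
  if (rng == 0) return(cycle_events(numeric(0), numeric(0)))
  ex <- alternating_extrema(v, min_prominence_mm)
  t <- (ex$idx - 1) / trace$fps
  cycle_events(open_times = t[ex$type > 0], close_times = t[ex$type < 0],
               open_values = v[ex$idx[ex$type > 0]],
               close_values = v[ex$idx[ex$type < 0]])
}

#' Splice an analysis clip around a swallow event
#'
#' Analysis episodes start at a swallow event: the analysis window spans
#' `clip_seconds` from the swallow frame, and `context_frames` extra frames
#' are attached to each end of the clip for frame-by-frame review (clamped
#' at the trace boundaries). Metrics are computed only on the central
#' analysis window.
#'
#' @param trace A [motion_trace()].
#' @param swallow_frame 0-based frame of the swallow event starting the clip.
#' @param clip_seconds Analysis window length: 2 (drinking) or 20 (eating).
#' @param context_frames Context frames added to each end (default 5).
#' @return List: `clip` (a [motion_trace()] covering context + window),
#'   `clip_start_frame`, `window_frames` = c(first, last) 0-based inclusive,
#'   `window_time` = c(start, end) seconds, half-open, on the original trace
#'   clock.
#' @export
splice_clip <- function(trace, swallow_frame, clip_seconds = 2,
                        context_frames = 5L) {
  stopifnot(inherits(trace, "motion_trace"))
  n <- length(trace$values)
  fps <- trace$fps
  if (swallow_frame < 0 || swallow_frame > n - 1L) {
    stop("swallow_frame outside trace", call. = FALSE)
  }
  ws <- as.integer(swallow_frame)
  we <- ws + as.integer(round(clip_seconds * fps)) - 1L
  if (we > n - 1L) {
    stop("analysis window extends past the end of the trace", call. = FALSE)
  }
  cs <- max(0L, ws - as.integer(context_frames))
  ce <- min(n - 1L, we + as.integer(context_frames))
  clip <- motion_trace(trace$values[(cs + 1L):(ce + 1L)], fps = fps,
                       units = trace$units)
  list(clip = clip,
       clip_start_frame = cs,
       window_frames = c(ws, we),
       window_time = c(ws / fps, (we + 1L) / fps))
}

count_in <- function(x, lo, hi_open) sum(x >= lo & x < hi_open)

value_at_time <- function(trace, t) {
  trace$values[pmin(pmax(round(t * trace$fps), 0), length(trace$values) - 1L) + 1L]
}

# mean phase slope close -> next open (opening) or open -> next close (closing)
phase_velocities <- function(events, trace, t0, t1) {
  cl <- events$close_times[events$close_times >= t0 & events$close_times < t1]
  op <- events$open_times[events$open_times >= t0 & events$open_times < t1]
  vel <- function(from, to) {
    out <- numeric(0)
    for (tf in from) {
      nxt <- to[to > tf]
      if (length(nxt) == 0) next
      tn <- nxt[1]
      dv <- value_at_time(trace, tn) - value_at_time(trace, tf)
      out <- c(out, abs(dv) / (tn - tf))
    }
    if (length(out)) mean(out) else NA_real_
  }
  list(opening = vel(cl, op), closing = vel(op, cl))
}

#' Drinking metrics from cycle events and swallow annotations
#'
#' Computes the standard drinking metrics over a 2 s analysis window:
#' \describe{
#'   \item{lick_rate}{cycles/s: closes counted in each half-open 1 s
#'     sub-window of the analysis window, then averaged.}
#'   \item{inter_lick_interval}{ms: mean of successive close-to-close
#'     intervals in the window.}
#'   \item{swallow_rate}{swallows/s: per-second swallow counts, averaged.}
#'   \item{inter_swallow_interval}{ms: mean successive swallow interval.}
#'   \item{lick_swallow_ratio}{mean number of cycles (by close time) in each
#'     half-open interval `(s_i, s_{i+1}]` between successive swallows.}
#'   \item{pharyngeal_transit_time}{ms: mean over swallows of
#'     `(esophagus_entry_frame - rest_frame) / fps`.}
#'   \item{jaw_opening_velocity, jaw_closing_velocity}{mm/s: mean per-phase
#'     slope, gape excursion divided by phase duration.}
#' }
#' Metrics that need swallows are reported as `NA` with a warning when the
#' annotations cannot support them (never as zero).
#'
#' @param events A [cycle_events()] on the original trace clock.
#' @param swallows Data.frame with columns `rest_frame`,
#'   `esophagus_entry_frame`, `swallow_frame` (0-based), or `NULL`.
#' @param trace The gape [motion_trace()].
#' @param window `c(start_s, end_s)` half-open analysis window (from
#'   [splice_clip()]'s `window_time`).
#' @return A `drinking_metrics` list.
#' @export
compute_drinking_metrics <- function(events, swallows, trace, window) {
  stopifnot(inherits(events, "cycle_events"), inherits(trace, "motion_trace"))
  fps <- trace$fps
  t0 <- window[1]; t1 <- window[2]
  secs <- floor(t1 - t0 + 1e-9)

  cl <- events$close_times[events$close_times >= t0 & events$close_times < t1]
  per_sec <- vapply(seq_len(secs) - 1,
                    function(k) count_in(cl, t0 + k, t0 + k + 1), numeric(1))
  lick_rate <- mean(per_sec)
  ili <- if (length(cl) >= 2) mean(diff(cl)) * 1000 else NA_real_

  if (!is.null(swallows) && nrow(swallows) > 0) {
    sw <- sort(swallows$swallow_frame / fps)
    sw <- sw[sw >= t0 & sw < t1]
  } else sw <- numeric(0)

  if (length(sw) == 0) {
    warning("no swallows in analysis window: ISI, lick-swallow ratio and PTT reported as missing",
            call. = FALSE)
    swallow_rate <- 0
    isi <- lsr <- ptt <- NA_real_
  } else {
    swallow_rate <- mean(vapply(seq_len(secs) - 1,
                                function(k) count_in(sw, t0 + k, t0 + k + 1),
                                numeric(1)))
    if (length(sw) >= 2) {
      isi <- mean(diff(sw)) * 1000
      lsr <- mean(vapply(seq_len(length(sw) - 1), function(i) {
        sum(events$close_times > sw[i] & events$close_times <= sw[i + 1])
      }, numeric(1)))
    } else {
      warning("fewer than two swallows in window: ISI and lick-swallow ratio missing",
              call. = FALSE)
      isi <- lsr <- NA_real_
    }
    in_win <- swallows$swallow_frame / fps >= t0 & swallows$swallow_frame / fps < t1
    ptt <- mean((swallows$esophagus_entry_frame[in_win] -
                   swallows$rest_frame[in_win]) / fps) * 1000
  }

  vel <- phase_velocities(events, trace, t0, t1)
  structure(list(lick_rate = lick_rate,
                 inter_lick_interval = ili,
                 swallow_rate = swallow_rate,
                 inter_swallow_interval = isi,
                 lick_swallow_ratio = lsr,
                 pharyngeal_transit_time = ptt,
                 jaw_opening_velocity = vel$opening,
                 jaw_closing_velocity = vel$closing),
            class = "drinking_metrics")
}

#' Eating metrics from cycle events, swallows and rotary-chew annotations
#'
#' Mastication rate is the mean cycle count over the (manually annotated)
#' 1 s rotary-chewing episodes; swallow rate is the mean of per-second
#' swallow counts over the 20 s window; the inter-swallow interval is in
#' seconds.
#'
#' @param events A [cycle_events()].
#' @param swallows Swallow annotation data.frame (see
#'   [compute_drinking_metrics()]) or `NULL`.
#' @param rotary_intervals Data.frame with `start_s`, `end_s` (1 s episodes
#'   of rotary mastication, inside the window); three are expected, fewer
#'   are used with a warning.
#' @param trace The gape [motion_trace()].
#' @param window `c(start_s, end_s)` half-open analysis window (20 s).
#' @return An `eating_metrics` list with `mastication_rate`, `swallow_rate`,
#'   `inter_swallow_interval` (s).
#' @export
compute_eating_metrics <- function(events, swallows, rotary_intervals,
                                   trace, window) {
  stopifnot(inherits(events, "cycle_events"), inherits(trace, "motion_trace"))
  fps <- trace$fps
  t0 <- window[1]; t1 <- window[2]
  secs <- floor(t1 - t0 + 1e-9)

  if (is.null(rotary_intervals) || nrow(rotary_intervals) == 0) {
    warning("no rotary mastication intervals: mastication rate missing",
            call. = FALSE)
    mast <- NA_real_
  } else {
    if (any(rotary_intervals$start_s < t0 | rotary_intervals$end_s > t1)) {
      stop("rotary interval outside analysis window", call. = FALSE)
    }
    if (nrow(rotary_intervals) < 3) {
      warning("fewer than three rotary mastication intervals; using the ",
              nrow(rotary_intervals), " available", call. = FALSE)
    }
    counts <- vapply(seq_len(nrow(rotary_intervals)), function(i) {
      count_in(events$close_times, rotary_intervals$start_s[i],
               rotary_intervals$end_s[i])
    }, numeric(1))
    mast <- mean(counts)
  }

  if (!is.null(swallows) && nrow(swallows) > 0) {
    sw <- sort(swallows$swallow_frame / fps)
    sw <- sw[sw >= t0 & sw < t1]
  } else sw <- numeric(0)
  swallow_rate <- mean(vapply(seq_len(secs) - 1,
                              function(k) count_in(sw, t0 + k, t0 + k + 1),
                              numeric(1)))
  isi <- if (length(sw) >= 2) mean(diff(sw)) else {
    warning("fewer than two swallows in window: ISI missing", call. = FALSE)
    NA_real_
  }

  structure(list(mastication_rate = mast, swallow_rate = swallow_rate,
                 inter_swallow_interval = isi),
            class = "eating_metrics")
}

#' Aggregate per-clip metrics into one record per mouse
#'
#' The standard protocol analyzes five 2 s drinking clips and one 20 s
#' eating clip per animal; the per-mouse value of each metric is the
#' unweighted mean across clips, with missing clip values dropped from the
#' mean (missing only if all clips are missing).
#'
#' @param drinking_clips List of 1-5 `drinking_metrics`.
#' @param eating_clip A single `eating_metrics`, or `NULL`.
#' @param mouse_id Optional identifier stored in the record.
#' @return A `metrics_record`: named list of aggregated metric values.
#' @export
aggregate_mouse <- function(drinking_clips, eating_clip = NULL,
                            mouse_id = NA_character_) {
  if (length(drinking_clips) == 0) {
    stop("at least one drinking clip is required", call. = FALSE)
  }
  stopifnot(all(vapply(drinking_clips, inherits, logical(1), "drinking_metrics")))
  dnames <- names(drinking_clips[[1]])
  drink <- vapply(dnames, function(nm) {
    vals <- vapply(drinking_clips, function(cl) cl[[nm]], numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
  names(drink) <- paste0("drinking_", dnames)

  eat <- c(eating_mastication_rate = NA_real_, eating_swallow_rate = NA_real_,
           eating_inter_swallow_interval = NA_real_)
  if (!is.null(eating_clip)) {
    stopifnot(inherits(eating_clip, "eating_metrics"))
    eat <- c(eating_mastication_rate = eating_clip$mastication_rate,
             eating_swallow_rate = eating_clip$swallow_rate,
             eating_inter_swallow_interval = eating_clip$inter_swallow_interval)
  }
  structure(c(list(mouse_id = mouse_id), as.list(c(drink, eat))),
            class = "metrics_record")
}

#' One-row data.frame view of a metrics record
#'
#' @param x A `metrics_record`.
#' @param ... Unused.
#' @return A one-row data.frame, suitable for rbinding across mice and
#'   writing as the per-mouse metrics CSV.
#' @export
as.data.frame.metrics_record <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}
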