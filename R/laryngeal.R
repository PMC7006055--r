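#' Detect respiratory cycles in glottal motion traces
#'
#' Per-side extrema (maximum abduction / maximum adduction) are detected on
#' each side's lateral trace; a shared cycle segmentation is taken from the
#' glottal width trace, whose maxima mark peak abduction (inspiration) and
#' whose minima mark peak adduction (expiration). Each consensus cycle
#' window runs from the width minimum preceding an abduction peak to the
#' minimum following it (clamped at the clip ends).
#'
#' @param left,right Lateral-coordinate [motion_trace()]s (px).
#' @param width Glottal width [motion_trace()] (px).
#' @param min_prominence_px Extremum prominence floor; default 20% of each
#'   trace's value range.
#' @return A `respiratory_cycles` object: `left`, `right` (per-side
#'   [cycle_events()]-like open/close times), `cycles` (data.frame `start_s`,
#'   `peak_s`, `end_s`, one row per consensus cycle), `n_left`, `n_right`
#'   (per-side cycle counts).
#' @export
detect_respiratory_cycles <- function(left, right, width,
                                      min_prominence_px = NULL) {
  stopifnot(inherits(left, "motion_trace"), inherits(right, "motion_trace"),
            inherits(width, "motion_trace"))
  side_events <- function(tr) {
    rng <- diff(range(tr$values))
    if (rng == 0) return(list(max_times = numeric(0), min_times = numeric(0)))
    prom <- if (is.null(min_prominence_px)) 0.2 * rng else min_prominence_px
    ex <- alternating_extrema(tr$values, prom)
    t <- (ex$idx - 1) / tr$fps
    list(max_times = t[ex$type > 0], min_times = t[ex$type < 0])
  }
  lv <- side_events(left)
  rv <- side_events(right)
  wv <- side_events(width)

  # per-side cycle count: one complete cycle per abduction/adduction pair
  count_side <- function(ev) {
    floor((length(ev$max_times) + length(ev$min_times)) / 2)
  }

  cycles <- data.frame(start_s = numeric(0), peak_s = numeric(0),
                       end_s = numeric(0))
  if (length(wv$max_times) > 0) {
    t_end <- (length(width$values) - 1) / width$fps
    cycles <- do.call(rbind, lapply(wv$max_times, function(pk) {
      before <- wv$min_times[wv$min_times < pk]
      after <- wv$min_times[wv$min_times > pk]
      data.frame(start_s = if (length(before)) max(before) else 0,
                 peak_s = pk,
                 end_s = if (length(after)) min(after) else t_end)
    }))
  }

  structure(list(left = lv, right = rv, width = wv, cycles = cycles,
                 n_left = count_side(lv), n_right = count_side(rv)),
            class = "respiratory_cycles")
}

#' @export
print.respiratory_cycles <- function(x, ...) {
  cat(sprintf("<respiratory_cycles> %d consensus cycles (left %.1f, right %.1f)\n",
              nrow(x$cycles), x$n_left, x$n_right))
  invisible(x)
}

window_idx <- function(trace, t_lo, t_hi) {
  t <- trace_times(trace)
  which(t >= t_lo - 1e-9 & t <= t_hi + 1e-9)
}

#' Laryngeal motion metrics over an analysis clip
#'
#' Computes the five standard laryngeal motion metrics from left/right
#' lateral glottal traces over a clip (10 s by default):
#' \describe{
#'   \item{mmrr}{mean motion range ratio: per consensus cycle, the ratio of
#'     the smaller to the larger side amplitude (lateral range within the
#'     cycle window), averaged; 1 = perfectly symmetric.}
#'   \item{occr}{open-close cycle ratio: right cycle count / left cycle
#'     count.}
#'   \item{mcorr}{motion correlation coefficient: Pearson correlation of the
#'     per-frame first differences of the left and right lateral coordinates
#'     on the shared image axis. -1 = anti-phase (normal), +1 = same
#'     direction (paradoxical), ~0 = little/no motion.}
#'   \item{vf_angle_max, vf_angle_min, vf_angle_mean}{per-cycle maximum and
#'     minimum of the angle (degrees) subtended at the dorsal commissure by
#'     the left and right points, averaged across cycles; `vf_angle_mean` is
#'     the mean of the per-cycle max/min midpoints.}
#'   \item{respiratory_rate}{consensus cycle count scaled to cycles/min.}
#' }
#'
#' @param cycles A [detect_respiratory_cycles()] result.
#' @param left,right Lateral-coordinate [motion_trace()]s.
#' @param tracks Optional named list of `marker_track`s (`left`, `right`,
#'   `commissure`) for the VF angle; if `NULL` the angle metrics are `NA`.
#' @param clip_seconds Clip length used for the rate conversion (default 10).
#' @param mmrr_order `"min_max"` (smaller/larger, symmetric, <= 1; default)
#'   or `"right_left"`.
#' @param occr_order `"right_left"` (default) or `"min_max"`.
#' @return A `laryngeal_metrics` list.
#' @export
compute_laryngeal_metrics <- function(cycles, left, right, tracks = NULL,
                                      clip_seconds = 10,
                                      mmrr_order = c("min_max", "right_left"),
                                      occr_order = c("right_left", "min_max")) {
  stopifnot(inherits(cycles, "respiratory_cycles"))
  mmrr_order <- match.arg(mmrr_order)
  occr_order <- match.arg(occr_order)

  cyc <- cycles$cycles
  mmrr <- NA_real_
  if (nrow(cyc) > 0) {
    ratios <- vapply(seq_len(nrow(cyc)), function(i) {
      il <- window_idx(left, cyc$start_s[i], cyc$end_s[i])
      ir <- window_idx(right, cyc$start_s[i], cyc$end_s[i])
      al <- diff(range(left$values[il]))
      ar <- diff(range(right$values[ir]))
      if (al == 0 || ar == 0) return(NA_real_)
      if (mmrr_order == "min_max") min(al, ar) / max(al, ar) else ar / al
    }, numeric(1))
    if (!all(is.na(ratios))) mmrr <- mean(ratios, na.rm = TRUE)
  }

  occr <- if (cycles$n_left > 0) {
    if (occr_order == "right_left") cycles$n_right / cycles$n_left
    else min(cycles$n_right, cycles$n_left) / max(cycles$n_right, cycles$n_left)
  } else NA_real_

  dl <- diff(left$values); dr <- diff(right$values)
  mcorr <- if (stats::sd(dl) == 0 || stats::sd(dr) == 0) NA_real_
           else stats::cor(dl, dr)

  vf_max <- vf_min <- vf_mean <- NA_real_
  if (!is.null(tracks)) {
    ang <- vf_angle_series(tracks$left, tracks$right, tracks$commissure)
    if (nrow(cyc) > 0) {
      fps <- left$fps
      per <- t(vapply(seq_len(nrow(cyc)), function(i) {
        idx <- which(trace_times(left) >= cyc$start_s[i] - 1e-9 &
                       trace_times(left) <= cyc$end_s[i] + 1e-9)
        range(ang[idx])
      }, numeric(2)))
      vf_min <- mean(per[, 1]); vf_max <- mean(per[, 2])
      vf_mean <- mean((per[, 1] + per[, 2]) / 2)
    }
  }

  respiratory_rate <- nrow(cyc) * 60 / clip_seconds

  structure(list(mmrr = mmrr, occr = occr, mcorr = mcorr,
                 vf_angle_max = vf_max, vf_angle_min = vf_min,
                 vf_angle_mean = vf_mean,
                 respiratory_rate = respiratory_rate),
            class = "laryngeal_metrics")
}

#' Per-frame vocal-fold angle
#'
#' Angle (degrees) subtended at the dorsal commissure by the left and right
#' glottal points in each frame.
#'
#' @param left,right,commissure `marker_track`s of equal length.
#' @return Numeric vector, degrees.
#' @export
vf_angle_series <- function(left, right, commissure) {
  vl <- left$positions - commissure$positions
  vr <- right$positions - commissure$positions
  num <- rowSums(vl * vr)
  den <- sqrt(rowSums(vl^2) * rowSums(vr^2))
  if (any(den == 0)) {
    stop("degenerate geometry: a point coincides with the commissure",
         call. = FALSE)
  }
  acos(pmin(pmax(num / den, -1), 1)) * 180 / pi
}

#' Laryngeal adductor reflex annotation
#'
#' @param present Was a reflex response observed (manual annotation)?
#' @param start_frame,end_frame 0-based frames bracketing the response
#'   (required when `present`).
#' @return A `lar_response` list.
#' @export
lar_response <- function(present, start_frame = NA_integer_,
                         end_frame = NA_integer_) {
  if (isTRUE(present)) {
    if (is.na(start_frame) || is.na(end_frame)) {
      stop("start_frame and end_frame are required when present = TRUE",
           call. = FALSE)
    }
    if (end_frame < start_frame) {
      stop("end_frame must be >= start_frame", call. = FALSE)
    }
  }
  structure(list(present = isTRUE(present),
                 start_frame = as.integer(start_frame),
                 end_frame = as.integer(end_frame)),
            class = "lar_response")
}

#' Laryngeal adductor reflex duration
#'
#' Duration in ms from the annotated start and end frames of a reflex
#' response; `NA` (missing, not zero) when no response was present.
#'
#' @param resp A [lar_response()].
#' @param fps Frames per second of the endoscopic video.
#' @return Duration in ms, a multiple of `1000 / fps`.
#' @examples
#' lar_duration(lar_response(TRUE, 100, 115), fps = 30)  # 500 ms
#' @export
lar_duration <- function(resp, fps = 30) {
  stopifnot(inherits(resp, "lar_response"))
  if (!resp$present) return(NA_real_)
  (resp$end_frame - resp$start_frame) / fps * 1000
}
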