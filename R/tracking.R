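#' Pixel-to-mm calibration from a traced calibration bar
#'
#' Fluoroscopic recordings include a radio-opaque bar of known physical
#' length (10 mm) at the top of the frame; manual tracing of that bar in the
#' first frame gives the scale used to convert marker distances to mm.
#'
#' @param bar_length_px Traced bar length in pixels, > 0.
#' @param bar_length_mm Physical bar length in mm (default 10).
#' @return A `calibration_scale` list with `mm_per_pixel` and
#'   `source_length_px`.
#' @examples
#' calibrate_scale(100)$mm_per_pixel  # 0.1
#' @export
calibrate_scale <- function(bar_length_px, bar_length_mm = 10) {
  if (!is.numeric(bar_length_px) || length(bar_length_px) != 1L ||
      bar_length_px <= 0) {
    stop("bar_length_px must be a single positive number", call. = FALSE)
  }
  if (bar_length_mm <= 0) stop("bar_length_mm must be > 0", call. = FALSE)
  structure(list(mm_per_pixel = bar_length_mm / bar_length_px,
                 source_length_px = bar_length_px),
            class = "calibration_scale")
}

# Extract the (2h+1)^2 patch centered at integer pixel (x, y), 0-based.
# Errors if the patch leaves the frame.
extract_patch <- function(frame, x, y, half) {
  h <- nrow(frame); w <- ncol(frame)
  if (x - half < 0 || x + half > w - 1 || y - half < 0 || y + half > h - 1) {
    stop("patch extends outside frame", call. = FALSE)
  }
  frame[(y - half + 1):(y + half + 1), (x - half + 1):(x + half + 1)]
}

# Normalized cross-correlation of a template against same-size patch.
ncc_score <- function(patch, template) {
  p <- patch - mean(patch)
  t <- template - mean(template)
  den <- sqrt(sum(p^2) * sum(t^2))
  if (den == 0) return(0)
  sum(p * t) / den
}

# Quadratic sub-pixel refinement from scores at offsets -1, 0, +1.
parabolic_offset <- function(sm1, s0, sp1) {
  den <- sm1 - 2 * s0 + sp1
  if (den >= 0) return(0)  # not a proper local maximum
  off <- 0.5 * (sm1 - sp1) / den
  max(min(off, 0.5), -0.5)
}

#' Track high-contrast markers across video frames
#'
#' Template tracking by normalized cross-correlation: a square patch around
#' each manually placed first-frame marker is the (fixed, never updated)
#' template; in each subsequent frame the best integer match is searched
#' within `search_radius_px` of the previous position and refined to
#' sub-pixel precision by fitting a parabola to the correlation scores along
#' each axis. Per-frame confidence is the NCC score clipped to \[0, 1\];
#' tracking aborts with an error naming the frame if confidence falls below
#' `confidence_floor`.
#'
#' @param frames List of grayscale matrices (values in \[0, 1\]), >= 2 frames.
#' @param initial_positions Named list of `(x, y)` marker positions in frame
#'   0 (0-based pixel coordinates, origin top-left, x right, y down).
#' @param template_half_width_px Template half width `h`; the template is
#'   `(2h+1) x (2h+1)` px (default 5).
#' @param search_radius_px Maximum per-frame displacement searched (default 8).
#' @param confidence_floor Minimum acceptable NCC score (default 0.5).
#' @return Named list of `marker_track` objects, each with `label`,
#'   `positions` (n x 2 matrix of x, y) and `confidence` (length n).
#' @export
track_markers <- function(frames, initial_positions,
                          template_half_width_px = 5L,
                          search_radius_px = 8L,
                          confidence_floor = 0.5) {
  if (length(frames) < 2L) stop("need at least 2 frames", call. = FALSE)
  half <- as.integer(template_half_width_px)
  sr <- as.integer(search_radius_px)
  n <- length(frames)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])

  out <- vector("list", length(initial_positions))
  names(out) <- names(initial_positions)
  for (mi in seq_along(initial_positions)) {
    p0 <- round(as.numeric(initial_positions[[mi]]))
    if (p0[1] < 0 || p0[1] > w - 1 || p0[2] < 0 || p0[2] > h - 1) {
      stop("initial position outside frame 0", call. = FALSE)
    }
    template <- extract_patch(frames[[1]], p0[1], p0[2], half)
    pos <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
    conf <- numeric(n)
    pos[1, ] <- p0
    conf[1] <- 1
    prev <- p0
    for (fi in 2:n) {
      frame <- frames[[fi]]
      # candidate integer centers whose template patch stays inside the frame
      cxs <- max(prev[1] - sr, half):min(prev[1] + sr, w - 1 - half)
      cys <- max(prev[2] - sr, half):min(prev[2] + sr, h - 1 - half)
      if (length(cxs) == 0 || length(cys) == 0) {
        stop(sprintf("tracking lost for marker '%s' at frame %d: search window left the frame",
                     names(out)[mi] %||% as.character(mi), fi - 1L), call. = FALSE)
      }
      scores <- matrix(-Inf, length(cys), length(cxs))
      for (iy in seq_along(cys)) {
        for (ix in seq_along(cxs)) {
          scores[iy, ix] <- ncc_score(
            extract_patch(frame, cxs[ix], cys[iy], half), template)
        }
      }
      best <- which(scores == max(scores), arr.ind = TRUE)[1, ]
      score <- scores[best[1], best[2]]
      if (score < confidence_floor) {
        stop(sprintf("tracking lost for marker '%s' at frame %d: best match score %.3f below floor %.2f",
                     names(out)[mi] %||% as.character(mi), fi - 1L, score,
                     confidence_floor), call. = FALSE)
      }
      bx <- cxs[best[2]]; by <- cys[best[1]]
      # sub-pixel refinement along each axis where neighbors exist
      dx <- dy <- 0
      if (best[2] > 1 && best[2] < length(cxs)) {
        dx <- parabolic_offset(scores[best[1], best[2] - 1], score,
                               scores[best[1], best[2] + 1])
      }
      if (best[1] > 1 && best[1] < length(cys)) {
        dy <- parabolic_offset(scores[best[1] - 1, best[2]], score,
                               scores[best[1] + 1, best[2]])
      }
      pos[fi, ] <- c(bx + dx, by + dy)
      conf[fi] <- max(min(score, 1), 0)
      prev <- c(bx, by)
    }
    out[[mi]] <- structure(list(label = names(out)[mi],
                                positions = pos, confidence = conf),
                           class = "marker_track")
  }
  out
}

#' Construct a marker track from known positions
#'
#' Convenience constructor used when positions come from a file or a
#' synthetic-truth object rather than from [track_markers()].
#'
#' @param positions n x 2 matrix (or 2-column data.frame) of x, y pixel
#'   coordinates, 0-based, origin top-left.
#' @param label Marker label.
#' @param confidence Optional per-frame confidence (default 1).
#' @return A `marker_track`.
#' @export
marker_track <- function(positions, label = "marker", confidence = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 2)
  colnames(positions) <- c("x", "y")
  if (is.null(confidence)) confidence <- rep(1, nrow(positions))
  stopifnot(length(confidence) == nrow(positions))
  structure(list(label = label, positions = positions, confidence = confidence),
            class = "marker_track")
}

#' Calibrated jaw-gape trace from upper and lower jaw marker tracks
#'
#' Per frame, the Euclidean distance in pixels between the upper and lower
#' jaw markers is converted to mm with the calibration scale.
#'
#' @param upper,lower `marker_track`s of equal length.
#' @param scale A [calibrate_scale()] result.
#' @param fps Frames per second of the source video.
#' @return A [motion_trace()] in mm.
#' @export
jaw_gape_trace <- function(upper, lower, scale, fps) {
  stopifnot(inherits(upper, "marker_track"), inherits(lower, "marker_track"),
            inherits(scale, "calibration_scale"))
  if (nrow(upper$positions) != nrow(lower$positions)) {
    stop("upper and lower tracks must have the same number of frames",
         call. = FALSE)
  }
  d <- sqrt(rowSums((upper$positions - lower$positions)^2))
  motion_trace(d * scale$mm_per_pixel, fps = fps, units = "mm")
}

#' Equidistant adjustment of the glottal edge points
#'
#' The left and right glottal-edge markers are adjusted to be equidistant
#' from the dorsal commissure, using the farther point as the reference: the
#' nearer point is moved outward along the ray from the commissure through
#' it, to the distance of the farther point; the farther point is unchanged.
#' The operation is idempotent.
#'
#' @param left,right,commissure Numeric `(x, y)` positions.
#' @return List with adjusted `left` and `right`.
#' @examples
#' adjust_glottal_points(c(-12, 0), c(10, 0), c(0, 0))$right  # c(12, 0)
#' @export
adjust_glottal_points <- function(left, right, commissure) {
  left <- as.numeric(left); right <- as.numeric(right)
  commissure <- as.numeric(commissure)
  vl <- left - commissure
  vr <- right - commissure
  dl <- sqrt(sum(vl^2)); dr <- sqrt(sum(vr^2))
  if (dl == 0 || dr == 0) {
    stop("degenerate geometry: a glottal point coincides with the commissure",
         call. = FALSE)
  }
  if (dl >= dr) {
    right <- commissure + vr * (dl / dr)
  } else {
    left <- commissure + vl * (dr / dl)
  }
  list(left = left, right = right)
}

#' Lateral glottal coordinate traces relative to the glottal axis
#'
#' The glottal axis is fixed from frame 0 as the bisector of the angle at the
#' commissure between the left and right points. Each point's per-frame
#' lateral coordinate is its signed perpendicular distance from that axis
#' (left negative, right positive); the width trace is the Euclidean
#' left-right distance. Because the axis is derived from the tracks
#' themselves, the traces are invariant to global translation and rotation
#' of all three tracks.
#'
#' @param left,right,commissure `marker_track`s of equal length.
#' @param fps Frames per second.
#' @return List of [motion_trace()]s: `left`, `right` (lateral coordinate,
#'   px) and `width` (px).
#' @export
glottal_lateral_traces <- function(left, right, commissure, fps) {
  stopifnot(inherits(left, "marker_track"), inherits(right, "marker_track"),
            inherits(commissure, "marker_track"))
  n <- nrow(left$positions)
  if (nrow(right$positions) != n || nrow(commissure$positions) != n) {
    stop("all three tracks must have the same number of frames", call. = FALSE)
  }
  c0 <- commissure$positions[1, ]
  ul <- left$positions[1, ] - c0
  ur <- right$positions[1, ] - c0
  nl <- sqrt(sum(ul^2)); nr <- sqrt(sum(ur^2))
  if (nl == 0 || nr == 0) {
    stop("degenerate geometry: a glottal point coincides with the commissure in frame 0",
         call. = FALSE)
  }
  axis <- ul / nl + ur / nr
  if (sqrt(sum(axis^2)) < 1e-12) {
    stop("degenerate geometry: left and right are antipodal about the commissure",
         call. = FALSE)
  }
  axis <- axis / sqrt(sum(axis^2))
  # normal to the axis, oriented so the frame-0 right point is positive
  nrm <- c(-axis[2], axis[1])
  if (sum(nrm * ur) < 0) nrm <- -nrm

  lat <- function(p) as.numeric((p[, 1] - c0[1]) * nrm[1] + (p[, 2] - c0[2]) * nrm[2])
  width <- sqrt(rowSums((left$positions - right$positions)^2))
  list(left = motion_trace(lat(left$positions), fps = fps, units = "px"),
       right = motion_trace(lat(right$positions), fps = fps, units = "px"),
       width = motion_trace(width, fps = fps, units = "px"))
}

#' Write marker tracks to CSV
#'
#' One row per frame per marker: `frame` (0-based), `label`, `x`, `y`,
#' `confidence`. Coordinates are 0-based, origin top-left, y down.
#'
#' @param tracks Named list of `marker_track`s.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_marker_tracks <- function(tracks, path) {
  dfs <- lapply(tracks, function(tr) {
    data.frame(frame = seq_len(nrow(tr$positions)) - 1L,
               label = tr$label,
               x = tr$positions[, 1], y = tr$positions[, 2],
               confidence = tr$confidence)
  })
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' Write / read grayscale video frames as numbered PNG files
#'
#' @param frames List of grayscale matrices in \[0, 1\].
#' @param dir Directory (created if missing); frames are written as
#'   `frame_0000.png`, `frame_0001.png`, ...
#' @return `write_frames_png` returns the directory invisibly;
#'   `read_frames_png` returns the list of matrices.
#' @export
write_frames_png <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]],
                  file.path(dir, sprintf("frame_%04d.png", i - 1L)))
  }
  invisible(dir)
}

#' @rdname write_frames_png
#' @export
read_frames_png <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no frame PNGs found in ", dir, call. = FALSE)
  lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
}
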