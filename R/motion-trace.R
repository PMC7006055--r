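#' Kinematic scalar time series sampled at a fixed frame rate
#'
#' A `motion_trace` holds one scalar kinematic signal per video frame: jaw
#' gape in mm for fluoroscopy, or a lateral glottal coordinate in px for
#' endoscopy. Frames are 0-based; frame `f` is sampled at time `f / fps`
#' seconds.
#'
#' @param values Numeric vector, one finite value per frame.
#' @param fps Frames per second (> 0).
#' @param units Unit tag, e.g. `"mm"` or `"px"`.
#' @return An object of class `motion_trace` with fields `values`, `fps`,
#'   `units`.
#' @examples
#' tr <- motion_trace(sin(seq(0, 2 * pi, length.out = 60)), fps = 30, units = "mm")
#' trace_times(tr)[1:3]
#' @export
motion_trace <- function(values, fps, units = "mm") {
  values <- as.numeric(values)
  if (!all(is.finite(values))) {
    stop("motion_trace values must all be finite", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("fps must be a single positive number", call. = FALSE)
  }
  structure(list(values = values, fps = fps, units = units),
            class = "motion_trace")
}

#' @export
length.motion_trace <- function(x) length(x$values)

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frames @ %g fps [%s], range %.3g..%.3g\n",
              length(x$values), x$fps, x$units,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Frame timestamps of a motion trace
#'
#' @param trace A [motion_trace()].
#' @return Numeric vector of times in seconds, frame `f` at `f / fps`.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "motion_trace"))
  (seq_along(trace$values) - 1) / trace$fps
}

#' Write / read a motion trace as CSV
#'
#' The CSV has columns `frame_index` (0-based), `time_s`, `value`; `fps` and
#' `units` are recovered from the data on read.
#'
#' @param trace A [motion_trace()].
#' @param path File path.
#' @param units Unit tag assumed on read.
#' @return `write_motion_trace` returns `path` invisibly; `read_motion_trace`
#'   returns a [motion_trace()].
#' @export
write_motion_trace <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  df <- data.frame(frame_index = seq_along(trace$values) - 1L,
                   time_s = trace_times(trace),
                   value = trace$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_trace
#' @export
read_motion_trace <- function(path, units = "mm") {
  df <- utils::read.csv(path)
  stopifnot(all(c("frame_index", "time_s", "value") %in% names(df)))
  if (nrow(df) < 2L) stop("trace CSV must have at least 2 frames", call. = FALSE)
  fps <- 1 / stats::median(diff(df$time_s))
  motion_trace(df$value, fps = fps, units = units)
}

# Run code with a local RNG state seeded from `seed`; the caller's RNG
# stream is untouched, so generators are deterministic and side-effect free.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
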