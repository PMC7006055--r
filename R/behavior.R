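#' Validate a home-cage behavior event log
#'
#' Consistency linter for event logs (class, start_s, duration_s): checks
#' chronological ordering, non-overlap of events, non-negative durations and
#' that every event lies within the recording. Substitutes for manual
#' spot-checking of the source video.
#'
#' @param log Data.frame with `class`, `start_s`, `duration_s`.
#' @param total_hours Recording length in hours.
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
check_behavior_log <- function(log, total_hours = 72) {
  stopifnot(all(c("class", "start_s", "duration_s") %in% names(log)))
  if (nrow(log) == 0) return(invisible(TRUE))
  if (any(log$duration_s < 0)) stop("negative event duration", call. = FALSE)
  if (is.unsorted(log$start_s)) stop("events not in chronological order", call. = FALSE)
  ends <- log$start_s + log$duration_s
  if (any(log$start_s < 0) || any(ends > total_hours * 3600 + 1e-9)) {
    stop("event outside the recording period", call. = FALSE)
  }
  if (nrow(log) > 1 && any(log$start_s[-1] < ends[-nrow(log)] - 1e-9)) {
    stop("overlapping events", call. = FALSE)
  }
  invisible(TRUE)
}

#' Bin behavior events into fixed periods
#'
#' Splits the recording into `total_hours / bin_hours` equal bins (three
#' 24 h bins for the standard 72 h recording). An event belongs to the bin
#' containing its start time and its whole duration is credited to that bin
#' (events are never split across bins).
#'
#' @param log Behavior event log (`class`, `start_s`, `duration_s`).
#' @param bin_hours Bin length in hours (default 24).
#' @param total_hours Recording length in hours (default 72); must be a
#'   multiple of `bin_hours`.
#' @return A `binned_events` list: `events` (the log plus a 1-based `bin`
#'   column), `n_bins`, `bin_hours`.
#' @export
bin_events <- function(log, bin_hours = 24, total_hours = 72) {
  stopifnot(all(c("class", "start_s", "duration_s") %in% names(log)))
  if (total_hours %% bin_hours != 0) {
    stop("total_hours must be a multiple of bin_hours", call. = FALSE)
  }
  n_bins <- as.integer(total_hours / bin_hours)
  if (nrow(log) > 0) {
    if (any(log$start_s < 0) || any(log$start_s >= total_hours * 3600)) {
      stop("event start beyond the recording period", call. = FALSE)
    }
    log$bin <- as.integer(floor(log$start_s / (bin_hours * 3600))) + 1L
  } else {
    log$bin <- integer(0)
  }
  structure(list(events = log, n_bins = n_bins, bin_hours = bin_hours),
            class = "binned_events")
}

#' Unit conversions for behavior summaries
#'
#' The per-mouse bin means are reported in converted units: bin-mean event
#' counts as events/hour (divide by the bin length in hours) and bin-mean
#' cumulative durations as minutes per bin (divide seconds by 60).
#'
#' @param mean_per_bin Mean events per bin.
#' @param bin_hours Bin length in hours (default 24).
#' @param mean_seconds_per_bin Mean cumulative duration per bin, seconds.
#' @return Converted value.
#' @examples
#' events_per_hour(82.32)    # 3.43
#' minutes_per_bin(107.40)   # 1.79
#' @export
events_per_hour <- function(mean_per_bin, bin_hours = 24) {
  mean_per_bin / bin_hours
}

#' @rdname events_per_hour
#' @export
minutes_per_bin <- function(mean_seconds_per_bin) {
  mean_seconds_per_bin / 60
}

#' Summarize binned behavior events per class
#'
#' Per class and bin: frequency (event count) and cumulative duration
#' (seconds). Per mouse: the unweighted mean over bins, plus the converted
#' units events/hour and minutes/bin.
#'
#' @param binned A [bin_events()] result.
#' @param classes Optional character vector fixing the classes (and order)
#'   to report; defaults to the classes present.
#' @return A `behavior_summary` list: `per_bin` (data.frame `class`, `bin`,
#'   `frequency`, `duration_s`) and `summary` (data.frame `class`,
#'   `mean_frequency_per_bin`, `mean_duration_s_per_bin`, `events_per_hour`,
#'   `minutes_per_bin`).
#' @export
summarize_behavior <- function(binned, classes = NULL) {
  stopifnot(inherits(binned, "binned_events"))
  ev <- binned$events
  if (is.null(classes)) classes <- sort(unique(as.character(ev$class)))
  grid <- expand.grid(class = classes, bin = seq_len(binned$n_bins),
                      stringsAsFactors = FALSE)
  per_bin <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sel <- ev$class == grid$class[i] & ev$bin == grid$bin[i]
    data.frame(class = grid$class[i], bin = grid$bin[i],
               frequency = sum(sel),
               duration_s = sum(ev$duration_s[sel]))
  }))
  summary <- do.call(rbind, lapply(classes, function(cls) {
    rows <- per_bin[per_bin$class == cls, ]
    mf <- mean(rows$frequency)
    md <- mean(rows$duration_s)
    data.frame(class = cls,
               mean_frequency_per_bin = mf,
               mean_duration_s_per_bin = md,
               events_per_hour = events_per_hour(mf, binned$bin_hours),
               minutes_per_bin = minutes_per_bin(md))
  }))
  structure(list(per_bin = per_bin, summary = summary),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}
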