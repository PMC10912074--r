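#' Acquisition frame schedule
#'
#' A frame schedule is the ordered list of acquisition frames of a dynamic
#' whole-body PET study, each frame an interval `[start, end]` in minutes
#' post-injection. Frames must be strictly increasing and non-overlapping;
#' gaps (e.g. a mid-scan intermission while the patient rests) are allowed.
#'
#' @param start,end Numeric vectors of frame start/end times in minutes.
#' @param labels Optional character vector of per-frame pass labels.
#' @return An object of class `frame_schedule` with elements `start`, `end`,
#'   `mid` (frame mid-times), `dur` (frame durations) and `labels`.
#' @export
frame_schedule <- function(start, end, labels = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != length(end) || length(start) == 0L)
    stop("start and end must be non-empty vectors of equal length")
  if (any(start < 0)) stop("frame times must be >= 0")
  if (any(end <= start)) stop("every frame must have end > start")
  # tolerance of 1e-9 min absorbs text round-trip rounding of boundaries
  if (any(diff(start) <= 0) ||
      any(start[-1] < end[-length(end)] - 1e-9))
    stop("frames must be strictly increasing and non-overlapping")
  if (!is.null(labels) && length(labels) != length(start))
    stop("labels must match the number of frames")
  structure(
    list(start = start, end = end, mid = (start + end) / 2,
         dur = end - start, labels = labels),
    class = "frame_schedule"
  )
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, %.1f-%.1f min, %.1f min scanned\n",
              length(x$start), min(x$start), max(x$end), sum(x$dur)))
  invisible(x)
}

#' Number of frames in a schedule
#' @param schedule A `frame_schedule`.
#' @return Integer frame count.
#' @export
n_frames <- function(schedule) length(schedule$start)

#' Default dynamic whole-body acquisition schedule
#'
#' The default schedule mirrors a two-session dynamic whole-body protocol:
#' a 6-min dynamic scan over the chest (12 x 10 s then 4 x 60 s frames,
#' chosen fine enough to resolve the bolus peak), 7 x 2 min whole-body
#' passes, 10 x 5 min passes ending at 70 min, a 10 min intermission, and
#' 8 x 5 min passes from 80 to 120 min. Frame boundaries align exactly with
#' the 40-70 min Patlak window and the 60-70 min SUV window.
#'
#' @return A [frame_schedule()].
#' @export
default_schedule <- function() {
  sec <- c(rep(10, 12),                 # 12 x 10 s
           rep(60, 4),                  # 4 x 60 s
           rep(120, 7),                 # 7 x 2 min
           rep(300, 10))                # 10 x 5 min, first session ends at 70
  end_s <- cumsum(sec)
  start <- c(c(0, end_s[-length(end_s)]), seq(4800, 6900, by = 300)) / 60
  end <- c(end_s, seq(5100, 7200, by = 300)) / 60   # 8 x 5 min post-pause
  labels <- c(rep("early-dynamic", 16),
              paste0("WB-pass-", 1:17),
              paste0("post-pause-pass-", 1:8))
  frame_schedule(start, end, labels)
}

#' Frames fully inside a time window
#'
#' @param schedule A `frame_schedule`.
#' @param window Numeric length-2 `c(t0, t1)` in minutes.
#' @return Integer indices of frames with `start >= t0` and `end <= t1`.
#' @export
frames_in_window <- function(schedule, window) {
  which(schedule$start >= window[1] - 1e-9 & schedule$end <= window[2] + 1e-9)
}

# index of the frame whose interval contains t (start <= t < end), NA if gap
frame_containing <- function(schedule, t) {
  i <- which(schedule$start <= t + 1e-9 & schedule$end > t + 1e-9)
  if (length(i) == 0L) NA_integer_ else i[1]
}

#' Time-activity curve container
#'
#' @param time Frame mid-times in minutes.
#' @param duration Frame durations in minutes.
#' @param activity Activity concentration per frame, kBq/mL.
#' @param label Optional region label.
#' @return An object of class `tac`.
#' @export
tac <- function(time, duration, activity, label = NULL) {
  time <- as.numeric(time); duration <- as.numeric(duration)
  activity <- as.numeric(activity)
  if (length(time) != length(duration) || length(time) != length(activity))
    stop("time, duration and activity must have equal length")
  if (any(diff(time) <= 0)) stop("mid-times must be increasing")
  if (any(duration <= 0)) stop("durations must be positive")
  structure(list(time = time, duration = duration, activity = activity,
                 label = label), class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac>%s %d frames, %.2f-%.2f min, peak %.3g kBq/mL\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              length(x$time), min(x$time), max(x$time), max(x$activity)))
  invisible(x)
}

# reconstruct a frame schedule from a TAC's mid-times and durations
schedule_from_tac <- function(x) {
  frame_schedule(x$time - x$duration / 2, x$time + x$duration / 2)
}
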