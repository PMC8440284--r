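#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule holds the start time and duration (both in minutes) of
#' every reconstructed frame. Frames must be contiguous, non-overlapping and
#' of positive duration.
#'
#' @param frame_start numeric vector of frame start times (minutes).
#' @param frame_duration numeric vector of frame durations (minutes).
#'
#' @return An object of class `frame_schedule` with elements `start`,
#'   `duration`, `mid` (frame midpoints) and `end`.
#' @examples
#' fs <- default_frame_schedule()
#' sum(fs$duration)  # 90 minutes
#' @export
frame_schedule <- function(frame_start, frame_duration) {
  frame_start <- as.numeric(frame_start)
  frame_duration <- as.numeric(frame_duration)
  if (length(frame_start) != length(frame_duration) || length(frame_start) == 0) {
    stop("frame_start and frame_duration must be non-empty and of equal length")
  }
  if (any(!is.finite(frame_start)) || any(!is.finite(frame_duration))) {
    stop("frame times must be finite")
  }
  if (any(frame_duration <= 0)) stop("frame durations must be positive")
  ends <- frame_start + frame_duration
  if (length(frame_start) > 1 &&
      max(abs(frame_start[-1] - ends[-length(ends)])) > 1e-9) {
    stop("frames must be contiguous and non-overlapping")
  }
  structure(
    list(start = frame_start, duration = frame_duration,
         mid = frame_start + frame_duration / 2, end = ends),
    class = "frame_schedule"
  )
}

#' Default 26-frame, 90-minute acquisition schedule
#'
#' Eight 15-s frames, three 1-min, five 2-min, five 5-min and five 10-min
#' frames, summing to 90 min.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(15 / 60, 8), rep(1, 3), rep(2, 5), rep(5, 5), rep(10, 5))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("PET frame schedule: %d frames, %.4g min total\n",
              length(x$start), sum(x$duration)))
  invisible(x)
}
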