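#' Frame schedule for a dynamic acquisition
#'
#' A frame schedule is a set of contiguous, non-overlapping acquisition frames
#' described by their start times and durations (both in seconds). Frames must
#' tile the acquisition window: each frame starts exactly where the previous
#' one ends.
#'
#' @param frame_start numeric vector of frame start times (s), non-negative,
#'   strictly increasing.
#' @param frame_duration numeric vector of frame durations (s), all positive.
#' @return A `frame_schedule` object (a data frame with columns `frame_start`
#'   and `frame_duration`).
#' @examples
#' frame_schedule(c(0, 5, 10), c(5, 5, 10))
#' @export
frame_schedule <- function(frame_start, frame_duration) {
  stopifnot(length(frame_start) == length(frame_duration),
            length(frame_start) >= 1L)
  if (any(frame_duration <= 0)) stop("all frame durations must be positive")
  if (frame_start[1L] < 0) stop("frame starts must be non-negative")
  ends <- frame_start + frame_duration
  n <- length(frame_start)
  if (n > 1L && any(abs(frame_start[-1L] - ends[-n]) > 1e-9)) {
    stop("frames must be contiguous and non-overlapping")
  }
  out <- data.frame(frame_start = frame_start, frame_duration = frame_duration)
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' The 39-frame, 60-minute dynamic PET frame schedule
#'
#' Builds the fixed variable-frame-length schedule used for dynamic
#' \[18F\]FDG-PET acquisition: 6 frames of 5 s, 6 of 10 s, 3 of 20 s, 5 of
#' 30 s, 5 of 60 s, 8 of 150 s and 6 of 300 s, for a total of exactly 3600 s.
#' The final six 300 s frames span \[1800, 3600) s and define the static-SUV
#' averaging window (see [suv_from_frames()]).
#'
#' @return A [frame_schedule()] with 39 frames totalling 3600 s.
#' @examples
#' sched <- pet_frame_schedule()
#' nrow(sched)                      # 39
#' sum(sched$frame_duration)        # 3600
#' @export
pet_frame_schedule <- function() {
  dur <- rep(c(5L, 10L, 20L, 30L, 60L, 150L, 300L),
             c(6L, 6L, 3L, 5L, 5L, 8L, 6L))
  frame_schedule(cumsum(c(0L, dur[-length(dur)])), dur)
}

#' CT-perfusion sampling times
#'
#' Sample times for the 3-minute dynamic contrast-enhanced CT acquisition:
#' every 2.8 s during the first minute (21 samples, t = 0 to 56 s) and every
#' 15 s for the following two minutes (t = 60 to 180 s). Unlike PET frames,
#' CTP samples are treated as instantaneous measurements, so this returns a
#' vector of times rather than a frame schedule.
#'
#' @return Sorted numeric vector of sample times in seconds, last sample 180 s.
#' @examples
#' times <- ctp_sampling_times()
#' diff(times)[1]   # 2.8
#' max(times)       # 180
#' @export
ctp_sampling_times <- function() {
  c(seq(0, by = 2.8, length.out = 21L), seq(60, 180, by = 15))
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %g s total\n",
              nrow(x), sum(x$frame_duration)))
  durs <- rle(x$frame_duration)
  cat("  ", paste(sprintf("%d x %g s", durs$lengths, durs$values),
                  collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Frame end times (s).
frame_ends <- function(schedule) schedule$frame_start + schedule$frame_duration
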