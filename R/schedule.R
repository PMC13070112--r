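#' Dynamic PET frame schedule
#'
#' A frame schedule is the time grid of a dynamic PET acquisition: contiguous,
#' non-overlapping frames of positive duration. Schedules are stored in
#' seconds (the unit scanners and TAC files use); all kinetic equations in
#' this package work in minutes and convert exactly once via
#' [frame_midpoints()] and [frame_durations_min()].
#'
#' @param duration_s numeric vector of frame durations in seconds.
#' @param start_s optional numeric vector of frame start times in seconds.
#'   Defaults to the cumulative schedule starting at 0. If supplied, frames
#'   must be contiguous: `start_s[j + 1] == start_s[j] + duration_s[j]`.
#' @return An object of class `frame_schedule` with fields `start_s`,
#'   `duration_s`, and `n_frames`.
#' @examples
#' sched <- frame_schedule(c(rep(20, 9), rep(60, 6), rep(120, 5), rep(360, 6)))
#' sum(sched$duration_s) # 3300 s = 55 min
#' @export
frame_schedule <- function(duration_s, start_s = NULL) {
  duration_s <- as.numeric(duration_s)
  if (length(duration_s) < 1L || any(!is.finite(duration_s)) || any(duration_s <= 0)) {
    stop("all frame durations must be finite and > 0")
  }
  implied <- cumsum(c(0, duration_s[-length(duration_s)]))
  if (is.null(start_s)) {
    start_s <- implied
  } else {
    start_s <- as.numeric(start_s)
    if (length(start_s) != length(duration_s)) {
      stop("start_s and duration_s must have equal length")
    }
    if (max(abs(start_s - start_s[1] - implied)) > 1e-6) {
      stop("frames must be contiguous and non-overlapping: start[j+1] = start[j] + duration[j]")
    }
  }
  structure(
    list(start_s = start_s, duration_s = duration_s, n_frames = length(duration_s)),
    class = "frame_schedule"
  )
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf(
    "<frame_schedule> %d frames, total %.0f s (%.1f min)\n",
    x$n_frames, sum(x$duration_s), sum(x$duration_s) / 60
  ))
  invisible(x)
}

#' The 26-frame MAO-B tracer schedule
#'
#' 9 x 20 s, 6 x 60 s, 5 x 120 s, 6 x 360 s: 26 frames totalling 55 min, the
#' acquisition used for the irreversible deuterated-deprenyl tracer.
#'
#' @return A [frame_schedule()].
#' @export
ded_frame_schedule <- function() {
  frame_schedule(c(rep(20, 9), rep(60, 6), rep(120, 5), rep(360, 6)))
}

#' The 18-frame DAT tracer schedule
#'
#' 9 x 120 s, 3 x 180 s, 3 x 260 s, 3 x 300 s: 18 frames totalling 55 min,
#' the acquisition used for the reversible DAT ligand.
#'
#' @return A [frame_schedule()].
#' @export
pe2i_frame_schedule <- function() {
  frame_schedule(c(rep(120, 9), rep(180, 3), rep(260, 3), rep(300, 3)))
}

#' Frame midpoints in minutes
#'
#' @param schedule a [frame_schedule()].
#' @return Numeric vector of frame midpoint times in minutes, strictly
#'   increasing.
#' @export
frame_midpoints <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  (schedule$start_s + schedule$duration_s / 2) / 60
}

#' Frame durations in minutes
#'
#' @param schedule a [frame_schedule()].
#' @return Numeric vector of frame durations in minutes.
#' @export
frame_durations_min <- function(schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  schedule$duration_s / 60
}
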