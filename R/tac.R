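#' Regional time-activity curve
#'
#' Framewise decay-corrected radioactivity concentration (kBq/ml) for one
#' region on a [frame_schedule()].
#'
#' @param schedule a [frame_schedule()].
#' @param activity numeric vector, one concentration per frame.
#' @param region region label (character scalar).
#' @return An object of class `tac`.
#' @export
tac <- function(schedule, activity, region = "region") {
  stopifnot(inherits(schedule, "frame_schedule"))
  activity <- as.numeric(activity)
  if (length(activity) != schedule$n_frames) {
    stop(sprintf(
      "activity has %d values but the schedule has %d frames",
      length(activity), schedule$n_frames
    ))
  }
  if (any(!is.finite(activity))) stop("activity values must be finite")
  structure(
    list(schedule = schedule, activity = activity, region = as.character(region)[1]),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf(
    "<tac> region '%s', %d frames, peak %.3g at %.2f min\n",
    x$region, x$schedule$n_frames, max(x$activity),
    frame_midpoints(x$schedule)[which.max(x$activity)]
  ))
  invisible(x)
}

#' Running integral of a time-activity curve
#'
#' Cumulative integral of the activity from time zero to each frame midpoint,
#' in kBq.min/ml. Two quadrature schemes are available:
#'
#' * `"frame"` (default): treats each frame's recorded activity as the frame
#'   average (which it is, for both scanner data and the simulator), so the
#'   integral over a whole frame is exactly `activity * duration`; the
#'   integral up to the frame midpoint is the sum of all previous frames plus
#'   half the current frame. This is the scheme the kinetic fitters use.
#' * `"trapezoid"`: trapezoidal rule over frame midpoints with an initial
#'   triangle from t = 0 to the first midpoint.
#'
#' Both schemes agree with the analytic integral of a smooth curve to well
#' under 1% on the 55-min schedules; `"frame"` is unbiased for frame-averaged
#' data and is what keeps noise-free model round-trips inside 1%.
#'
#' @param x a [tac()].
#' @param method `"frame"` or `"trapezoid"`.
#' @return Numeric vector, cumulative integral at each frame midpoint;
#'   nondecreasing for nonnegative activity.
#' @export
running_integral <- function(x, method = c("frame", "trapezoid")) {
  stopifnot(inherits(x, "tac"))
  method <- match.arg(method)
  a <- x$activity
  if (method == "frame") {
    dmin <- frame_durations_min(x$schedule)
    cumsum(a * dmin) - a * dmin / 2
  } else {
    t <- frame_midpoints(x$schedule)
    n <- length(a)
    out <- numeric(n)
    out[1] <- a[1] * t[1] / 2
    if (n > 1) {
      out[-1] <- out[1] + cumsum((a[-1] + a[-n]) / 2 * diff(t))
    }
    out
  }
}
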