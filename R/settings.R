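#' Acquisition settings for a tracking experiment
#'
#' Bundles the constants of the video acquisition: the frame interval, the
#' number of frames per recording and the physical pixel size. Defaults match
#' a 5-minute brightfield recording sampled every 0.5 s (601 frames) on a
#' camera with 0.16 micron pixels.
#'
#' @param frame_interval Time between consecutive frames, seconds. Must be
#'   positive.
#' @param n_frames Number of frames per trajectory. Must be at least 2.
#' @param pixel_size Physical size of one camera pixel, microns. Must be
#'   positive. Displacements below this size are unresolvable and are
#'   treated as pauses by [pause_fraction()].
#'
#' @return An object of class `acq_settings`: a list with fields
#'   `frame_interval`, `n_frames`, `pixel_size` and the derived `duration`
#'   (`(n_frames - 1) * frame_interval`, seconds).
#' @examples
#' s <- acq_settings()
#' s$duration # 300 s
#' @export
acq_settings <- function(frame_interval = 0.5, n_frames = 601, pixel_size = 0.16) {
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop("`frame_interval` must be a single positive number (seconds)", call. = FALSE)
  }
  if (!is.numeric(n_frames) || length(n_frames) != 1 || !is.finite(n_frames) ||
      n_frames < 2 || n_frames != round(n_frames)) {
    stop("`n_frames` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (microns)", call. = FALSE)
  }
  structure(
    list(
      frame_interval = as.numeric(frame_interval),
      n_frames = as.integer(n_frames),
      pixel_size = as.numeric(pixel_size),
      duration = (as.numeric(n_frames) - 1) * as.numeric(frame_interval)
    ),
    class = "acq_settings"
  )
}

#' @export
print.acq_settings <- function(x, ...) {
  cat(sprintf(
    "Acquisition settings: %d frames every %g s (duration %g s), pixel %g um\n",
    x$n_frames, x$frame_interval, x$duration, x$pixel_size
  ))
  invisible(x)
}

is_acq_settings <- function(x) inherits(x, "acq_settings")
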