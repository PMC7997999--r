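#' Construct a trajectory
#'
#' A trajectory is one tracked particle's time-ordered 2D positions together
#' with the acquisition settings that produced it. Positions are in microns;
#' times in seconds, on a regular grid of `settings$frame_interval` unless
#' the trajectory was read with gap tolerance (see [read_tracks()]).
#'
#' @param track_id Identifier (coerced to character).
#' @param x,y Numeric coordinate vectors, microns; equal length, all finite.
#' @param settings An [acq_settings()] object.
#' @param times Optional time vector, seconds. Defaults to a regular grid
#'   `(0, dt, 2 dt, ...)`. Must be strictly increasing.
#' @param provenance Optional list describing how the trajectory was
#'   generated (e.g. a [sim_params()] object); carried along unchanged.
#' @param gapped Logical: whether non-uniform frame spacing is permitted
#'   (set by the reader when gaps are tolerated).
#'
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(track_id, x, y, settings, times = NULL,
                       provenance = NULL, gapped = FALSE) {
  stopifnot(is_acq_settings(settings))
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < 1) stop("trajectory must contain at least one frame", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("trajectory positions must all be finite", call. = FALSE)
  }
  if (is.null(times)) {
    times <- (seq_along(x) - 1) * settings$frame_interval
  } else {
    times <- as.numeric(times)
    if (length(times) != length(x)) {
      stop("`times` must match the number of positions", call. = FALSE)
    }
    if (any(diff(times) <= 0)) {
      stop("`times` must be strictly increasing", call. = FALSE)
    }
    if (!gapped) {
      dt <- diff(times)
      if (length(dt) &&
          any(abs(dt - settings$frame_interval) > 1e-9 * settings$frame_interval)) {
        stop("frame spacing is not uniform; read with gap tolerance to permit gaps",
             call. = FALSE)
      }
    }
  }
  structure(
    list(
      track_id = as.character(track_id)[1],
      times = times,
      x = x,
      y = y,
      settings = settings,
      provenance = provenance,
      gapped = isTRUE(gapped)
    ),
    class = "trajectory"
  )
}

is_trajectory <- function(x) inherits(x, "trajectory")

assert_trajectory <- function(traj, min_frames = 2L) {
  if (!is_trajectory(traj)) stop("expected a `trajectory` object", call. = FALSE)
  if (length(traj$x) < min_frames) {
    stop(sprintf("trajectory '%s' has %d frame(s); at least %d required",
                 traj$track_id, length(traj$x), min_frames), call. = FALSE)
  }
  invisible(traj)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(is_trajectory(traj))
  length(traj$x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory '%s': %d frames over %g s", x$track_id,
              length(x$x), x$times[length(x$times)] - x$times[1]))
  if (!is.null(x$provenance$process)) cat(sprintf(" [%s]", x$provenance$process))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(
    track_id = x$track_id,
    frame = seq_along(x$x) - 1L,
    time_s = x$times,
    x_um = x$x,
    y_um = x$y,
    stringsAsFactors = FALSE
  )
}

# Step mask excluding steps that span a frame gap (gapped trajectories only).
valid_steps <- function(traj) {
  dt <- diff(traj$times)
  if (!traj$gapped) return(rep(TRUE, length(dt)))
  dt <= 1.5 * traj$settings$frame_interval
}

# Per-step Euclidean displacements (microns), one per consecutive frame pair.
step_lengths <- function(traj) {
  sqrt(diff(traj$x)^2 + diff(traj$y)^2)
}
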