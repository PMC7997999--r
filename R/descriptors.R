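#' Total distance traveled by a trajectory
#'
#' Sum of the Euclidean step lengths over all consecutive frame pairs,
#' computed on the coordinates as provided (apply [quantize_to_pixels()]
#' first to reproduce what a pixel-resolution tracking plugin reports). For
#' gap-tolerant trajectories, steps spanning a gap are excluded.
#'
#' @param traj A [trajectory()] with at least 2 frames.
#' @return Total path length, microns.
#' @export
total_distance <- function(traj) {
  assert_trajectory(traj)
  sum(step_lengths(traj)[valid_steps(traj)])
}

#' Euclidean (net) distance of a trajectory
#'
#' Straight-line distance between the position at the first frame and the
#' position at the last frame. Always bounded above by [total_distance()].
#'
#' @inheritParams total_distance
#' @return Net displacement, microns.
#' @export
euclidean_distance <- function(traj) {
  assert_trajectory(traj)
  n <- length(traj$x)
  sqrt((traj$x[n] - traj$x[1])^2 + (traj$y[n] - traj$y[1])^2)
}

#' Average distance per frame and average velocity
#'
#' The average distance is the total distance divided by the number of
#' frames (the literal plugin-report convention; the number of steps is one
#' less and is available via `divisor = "steps"`). The average velocity is
#' the average distance divided by the frame interval.
#'
#' @inheritParams total_distance
#' @param divisor `"frames"` (default, divides by the frame count) or
#'   `"steps"` (divides by the step count, `n_frames - 1`).
#' @return A list with `average_distance` (microns per frame) and
#'   `average_velocity` (microns per second).
#' @export
average_distance_and_velocity <- function(traj, divisor = c("frames", "steps")) {
  assert_trajectory(traj)
  divisor <- match.arg(divisor)
  n <- length(traj$x)
  denom <- if (divisor == "frames") n else n - 1L
  avg <- total_distance(traj) / denom
  list(average_distance = avg,
       average_velocity = avg / traj$settings$frame_interval)
}

#' Fraction of time a particle is paused
#'
#' A step counts as a pause when no movement is resolvable at the pixel
#' scale. In the default `"quantized"` mode, coordinates are first rounded
#' to the pixel grid and a step is paused iff the quantized displacement is
#' exactly zero; in `"threshold"` mode a step is paused iff the raw
#' displacement is below the pixel size. The fraction is paused steps over
#' total (valid) steps.
#'
#' @inheritParams total_distance
#' @param mode `"quantized"` or `"threshold"`.
#' @param pixel_size Pixel pitch, microns; defaults to the acquisition value.
#' @return Fraction in `[0, 1]`.
#' @export
pause_fraction <- function(traj, mode = c("quantized", "threshold"),
                           pixel_size = NULL) {
  assert_trajectory(traj)
  mode <- match.arg(mode)
  if (is.null(pixel_size)) pixel_size <- traj$settings$pixel_size
  keep <- valid_steps(traj)
  if (mode == "quantized") {
    q <- quantize_to_pixels(traj, pixel_size)
    paused <- (diff(q$x) == 0 & diff(q$y) == 0)[keep]
  } else {
    paused <- (step_lengths(traj) < pixel_size)[keep]
  }
  mean(paused)
}

#' Net radial direction of a trajectory relative to the nucleus
#'
#' Compares the particle's distance from the nucleus centre at the first and
#' last frame: `"centrifugal"` when the net radial distance grows by more
#' than `tie_tolerance`, `"centripetal"` when it shrinks by more, and
#' `"indeterminate"` otherwise. The tolerance (one pixel by default)
#' prevents noise-driven labels. A per-step majority-vote variant is
#' available with `method = "stepwise"`.
#'
#' @inheritParams total_distance
#' @param nucleus_center Numeric `c(x, y)`, microns.
#' @param tie_tolerance Radial change below which the direction is
#'   indeterminate, microns; default one pixel.
#' @param method `"net"` (first-to-last) or `"stepwise"` (majority of
#'   per-step radial changes).
#' @return One of `"centrifugal"`, `"centripetal"`, `"indeterminate"`.
#' @export
radial_direction <- function(traj, nucleus_center, tie_tolerance = NULL,
                             method = c("net", "stepwise")) {
  assert_trajectory(traj)
  method <- match.arg(method)
  nucleus_center <- as.numeric(nucleus_center)
  if (length(nucleus_center) != 2 || !all(is.finite(nucleus_center))) {
    stop("`nucleus_center` must be a finite (x, y) pair", call. = FALSE)
  }
  if (is.null(tie_tolerance)) tie_tolerance <- traj$settings$pixel_size
  r <- sqrt((traj$x - nucleus_center[1])^2 + (traj$y - nucleus_center[2])^2)
  if (method == "net") {
    dr <- r[length(r)] - r[1]
    if (dr > tie_tolerance) return("centrifugal")
    if (dr < -tie_tolerance) return("centripetal")
    return("indeterminate")
  }
  steps <- diff(r)[valid_steps(traj)]
  vote <- sum(sign(steps))
  if (vote > 0) "centrifugal" else if (vote < 0) "centripetal" else "indeterminate"
}

#' Summarize kinematic descriptors over a trajectory population
#'
#' Computes the per-trajectory descriptors (total, Euclidean and average
#' distance, average velocity, pause fraction and, when a nucleus centre is
#' supplied, radial direction) and population aggregates: mean and SD of
#' each numeric descriptor and the centrifugal/centripetal percentages among
#' non-indeterminate trajectories.
#'
#' @param trajs Non-empty list of [trajectory()] objects.
#' @param nucleus_center Optional `c(x, y)` for radial direction labels.
#' @param quantize Quantize coordinates to the pixel grid before computing
#'   distance descriptors (pause detection quantizes internally regardless).
#' @param pause_mode Passed to [pause_fraction()].
#' @param divisor Passed to [average_distance_and_velocity()].
#' @return A list of class `descriptor_summary` with `tracks` (one row per
#'   trajectory) and `aggregate` (one-row data frame of population
#'   statistics).
#' @export
summarize_population <- function(trajs, nucleus_center = NULL, quantize = FALSE,
                                 pause_mode = c("quantized", "threshold"),
                                 divisor = c("frames", "steps")) {
  if (!is.list(trajs) || length(trajs) == 0) {
    stop("`trajs` must be a non-empty list of trajectories", call. = FALSE)
  }
  pause_mode <- match.arg(pause_mode)
  divisor <- match.arg(divisor)
  rows <- lapply(trajs, function(tr) {
    assert_trajectory(tr)
    trd <- if (quantize) quantize_to_pixels(tr) else tr
    av <- average_distance_and_velocity(trd, divisor)
    data.frame(
      track_id = tr$track_id,
      total_distance = total_distance(trd),
      euclidean_distance = euclidean_distance(trd),
      average_distance = av$average_distance,
      average_velocity = av$average_velocity,
      pause_fraction = pause_fraction(tr, pause_mode),
      radial_direction = if (is.null(nucleus_center)) NA_character_ else
        radial_direction(trd, nucleus_center),
      stringsAsFactors = FALSE
    )
  })
  tracks <- do.call(rbind, rows)
  num <- c("total_distance", "euclidean_distance", "average_distance",
           "average_velocity", "pause_fraction")
  agg <- data.frame(n = nrow(tracks))
  for (col in num) {
    agg[[paste0("mean_", col)]] <- mean(tracks[[col]])
    agg[[paste0("sd_", col)]] <- stats::sd(tracks[[col]])
  }
  if (!is.null(nucleus_center)) {
    decided <- tracks$radial_direction[tracks$radial_direction != "indeterminate"]
    agg$n_directional_labelled <- length(decided)
    agg$pct_centrifugal <- if (length(decided)) 100 * mean(decided == "centrifugal") else NA_real_
    agg$pct_centripetal <- if (length(decided)) 100 * mean(decided == "centripetal") else NA_real_
  }
  structure(list(tracks = tracks, aggregate = agg), class = "descriptor_summary")
}

#' @export
print.descriptor_summary <- function(x, ...) {
  cat(sprintf("Descriptor summary for %d trajectories\n", nrow(x$tracks)))
  cat(sprintf("  mean total distance: %.3g um, mean pause fraction: %.3g\n",
              x$aggregate$mean_total_distance, x$aggregate$mean_pause_fraction))
  invisible(x)
}
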