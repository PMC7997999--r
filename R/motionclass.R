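# Convert a lag in seconds to an integer frame lag, requiring near-exact
# representability on the frame grid.
lag_to_frames <- function(tau, settings, duration) {
  m <- tau / settings$frame_interval
  if (abs(m - round(m)) > 1e-9) {
    stop(sprintf("lag %g s is not a multiple of the frame interval %g s",
                 tau, settings$frame_interval), call. = FALSE)
  }
  m <- as.integer(round(m))
  if (m < 1 || tau > duration + 1e-9) {
    stop(sprintf("lag %g s is outside the observable range", tau), call. = FALSE)
  }
  m
}

#' Second moments of displacement at a short and a long lag
#'
#' The pair `(mu2S, mu2L)` is the trajectory's time-averaged mean-square
#' displacement evaluated at a short lag `tau_S` and a long lag `tau_L`. The
#' two moments jointly separate directional from non-directional motion: for
#' Brownian motion their ratio is `tau_L / tau_S` in expectation (MSD linear
#' in lag), while for directional motion it is `(tau_L / tau_S)^2`.
#'
#' @param traj A [trajectory()].
#' @param tau_S,tau_L Short and long lags, seconds; multiples of the frame
#'   interval with `tau_S < tau_L <=` duration.
#' @return A list of class `moment_pair`: `mu2S`, `mu2L`, `tau_S`, `tau_L`,
#'   `track_id`.
#' @export
compute_moments <- function(traj, tau_S = 5, tau_L = 40) {
  assert_trajectory(traj, min_frames = 3L)
  if (traj$gapped) stop("moments require uniformly sampled trajectories", call. = FALSE)
  if (!(tau_S < tau_L)) stop("`tau_S` must be smaller than `tau_L`", call. = FALSE)
  dur <- traj$times[length(traj$times)] - traj$times[1]
  mS <- lag_to_frames(tau_S, traj$settings, dur)
  mL <- lag_to_frames(tau_L, traj$settings, dur)
  structure(
    list(mu2S = msd_at_lag(traj, mS), mu2L = msd_at_lag(traj, mL),
         tau_S = tau_S, tau_L = tau_L, track_id = traj$track_id),
    class = "moment_pair")
}

#' Second moments for every trajectory in a population
#'
#' @param trajs List of [trajectory()] objects.
#' @inheritParams compute_moments
#' @return Data frame with columns `track_id`, `mu2S`, `mu2L`, `s`
#'   (`log10(mu2L) - log10(mu2S)`, `NA` for zero moments).
#' @export
population_moments <- function(trajs, tau_S = 5, tau_L = 40) {
  rows <- lapply(trajs, function(tr) {
    mp <- compute_moments(tr, tau_S, tau_L)
    data.frame(track_id = tr$track_id, mu2S = mp$mu2S, mu2L = mp$mu2L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$s <- ifelse(out$mu2S > 0 & out$mu2L > 0,
                  log10(out$mu2L) - log10(out$mu2S), NA_real_)
  out
}

#' Calibrate directional/non-directional frontiers on a Brownian reference
#'
#' Frontiers are slope-1 lines in the `log10(mu2L)` vs `log10(mu2S)` plane,
#' i.e. levels of the scalar `s = log10(mu2L) - log10(mu2S)`. For Brownian
#' motion `s` is a pivot - its distribution does not depend on the diffusion
#' coefficient, because MSD is proportional to lag - which is what makes a
#' single pair of frontiers applicable to every population. Calibration
#' simulates `n_reference` Brownian trajectories (with localization noise
#' and pixel quantization matched to the analysis chain, so tracking
#' artifacts are reflected in the reference) and places the lower/upper
#' frontier at the `q_low`/`q_high` quantiles of `s`. Trajectories above the
#' upper frontier are classified directional; the band between the lines is
#' the classification uncertainty.
#'
#' @param settings An [acq_settings()].
#' @param tau_S,tau_L Moment lags, seconds.
#' @param q_low,q_high Quantile levels of the reference `s` distribution,
#'   `0 < q_low < q_high < 1`.
#' @param n_reference Number of reference trajectories (>= 1000).
#' @param D Reference diffusion coefficient, um^2/s (the calibrated offsets
#'   do not depend on it; it only sets the scale of the cloud).
#' @param noise_sigma Localization noise applied to the reference, microns.
#' @param quantize Pixel-quantize the reference trajectories.
#' @param seed Root seed for the reference simulation.
#' @return A list of class `frontiers`: offsets `c_low` and `c_high`, plus
#'   the full calibration record (quantiles, lags, `n_reference`, reference
#'   settings and seed, number of excluded degenerate trajectories).
#' @export
calibrate_frontiers <- function(settings = acq_settings(), tau_S = 5, tau_L = 40,
                                q_low = 0.5, q_high = 0.95, n_reference = 2000,
                                D = 0.01, noise_sigma = 0, quantize = FALSE,
                                seed = 1) {
  if (!(q_low > 0 && q_low < q_high && q_high < 1)) {
    stop("need 0 < q_low < q_high < 1", call. = FALSE)
  }
  if (n_reference < 1000) {
    stop("`n_reference` must be at least 1000 for stable quantiles", call. = FALSE)
  }
  if (D <= 0) stop("reference `D` must be positive", call. = FALSE)
  ref <- generate_population(
    list(list(params = sim_params("brownian", D = D, noise_sigma = noise_sigma),
              count = n_reference)),
    settings = settings, seed = seed, id_prefix = "ref")
  if (quantize) ref <- lapply(ref, quantize_to_pixels)
  mom <- population_moments(ref, tau_S, tau_L)
  s <- mom$s[is.finite(mom$s)]
  excluded <- nrow(mom) - length(s)
  if (excluded > 0.01 * n_reference) {
    stop(sprintf(
      "calibration failed: %d of %d reference trajectories had degenerate moments",
      excluded, n_reference), call. = FALSE)
  }
  structure(
    list(c_low = unname(stats::quantile(s, q_low)),
         c_high = unname(stats::quantile(s, q_high)),
         q_low = q_low, q_high = q_high, tau_S = tau_S, tau_L = tau_L,
         n_reference = n_reference, n_excluded = excluded, D = D,
         noise_sigma = noise_sigma, quantize = quantize, seed = seed,
         settings = settings),
    class = "frontiers")
}

#' @export
print.frontiers <- function(x, ...) {
  cat(sprintf(
    "Frontiers: c_low = %.4f (q = %g), c_high = %.4f (q = %g)\n  lags %g/%g s, %d Brownian reference trajectories (seed %d)\n",
    x$c_low, x$q_low, x$c_high, x$q_high, x$tau_S, x$tau_L, x$n_reference, x$seed))
  invisible(x)
}

#' Classify motion as directional, non-directional or intermediate
#'
#' Computes `s = log10(mu2L) - log10(mu2S)` and compares it to the
#' calibrated frontiers: `"D"` when `s` is strictly above the upper
#' frontier, `"ND"` when strictly below the lower, `"intermediate"` in the
#' closed band between them (a point exactly on a frontier is
#' intermediate). Zero-moment (e.g. stationary) trajectories are `"ND"`.
#'
#' @param moments A `moment_pair` from [compute_moments()], or a
#'   [trajectory()] (moments are then computed at the frontier lags).
#' @param frontiers A [calibrate_frontiers()] result.
#' @return `"D"`, `"ND"` or `"intermediate"`.
#' @export
classify_motion <- function(moments, frontiers) {
  stopifnot(inherits(frontiers, "frontiers"))
  if (is_trajectory(moments)) {
    moments <- compute_moments(moments, frontiers$tau_S, frontiers$tau_L)
  }
  if (!inherits(moments, "moment_pair")) {
    stop("`moments` must be a moment_pair or trajectory", call. = FALSE)
  }
  if (!is.finite(moments$mu2S) || !is.finite(moments$mu2L)) {
    stop("moments must be finite", call. = FALSE)
  }
  if (moments$mu2S <= 0 || moments$mu2L <= 0) return("ND")
  s <- log10(moments$mu2L) - log10(moments$mu2S)
  if (s > frontiers$c_high) "D" else if (s < frontiers$c_low) "ND" else "intermediate"
}

#' Count directional trajectories in a population
#'
#' Classifies every trajectory against a fixed, pre-calibrated pair of
#' frontiers (the same frontiers must be used for all populations compared)
#' and reports the three-way counts together with the directional range
#' `[n_D, n_D + n_intermediate]`, the between-frontier band acting as the
#' error bar on the directional count.
#'
#' @param trajs List of [trajectory()] objects.
#' @param frontiers A [calibrate_frontiers()] result; never recalibrated per
#'   population.
#' @return A list of class `directional_count`: `n`, `n_D`,
#'   `n_intermediate`, `n_ND`, `range` (length-2 integer), `labels`
#'   (per-trajectory factor).
#' @export
count_directional <- function(trajs, frontiers) {
  stopifnot(inherits(frontiers, "frontiers"))
  labels <- vapply(trajs, function(tr) classify_motion(tr, frontiers), "")
  labels <- factor(labels, levels = c("ND", "intermediate", "D"))
  nD <- sum(labels == "D")
  nI <- sum(labels == "intermediate")
  structure(
    list(n = length(labels), n_D = nD, n_intermediate = nI,
         n_ND = sum(labels == "ND"), range = c(nD, nD + nI), labels = labels),
    class = "directional_count")
}

#' @export
print.directional_count <- function(x, ...) {
  cat(sprintf(
    "Directional trajectories: %d-%d of %d (%.0f-%.0f%%); D = %d, intermediate = %d, ND = %d\n",
    x$range[1], x$range[2], x$n, 100 * x$range[1] / x$n, 100 * x$range[2] / x$n,
    x$n_D, x$n_intermediate, x$n_ND))
  invisible(x)
}
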