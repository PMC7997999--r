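# Time-averaged MSD at a single integer lag m (frames), using every
# overlapping ordered pair (t, t + m dt).
msd_at_lag <- function(traj, m) {
  n <- length(traj$x)
  dx <- traj$x[(m + 1):n] - traj$x[1:(n - m)]
  dy <- traj$y[(m + 1):n] - traj$y[1:(n - m)]
  mean(dx * dx + dy * dy)
}

#' Time-averaged mean-square displacement of a trajectory
#'
#' For each integer lag `m` with `m * dt <= max_lag_fraction * duration`,
#' the MSD is the mean squared displacement over all `n_frames - m`
#' overlapping ordered frame pairs: `MSD(tau) = <[r(t + tau) - r(t)]^2>`.
#' This is the single-trajectory (time-averaged) estimator; overlapping
#' pairs maximize the pair count per lag. Restricting lags to a fraction of
#' the duration (default one quarter) guards against the high variance of
#' long-lag estimates.
#'
#' @param traj A [trajectory()] with at least 3 frames and uniform spacing.
#' @param max_lag_fraction Largest lag as a fraction of the trajectory
#'   duration, in `(0, 1]`.
#' @return A data frame of class `msd_curve` with columns `lag` (seconds),
#'   `msd` (square microns) and `n_pairs`, plus attributes `track_id` and
#'   `settings`.
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.25) {
  assert_trajectory(traj, min_frames = 3L)
  if (traj$gapped) {
    stop("MSD requires uniformly sampled trajectories (no frame gaps)", call. = FALSE)
  }
  if (!is.numeric(max_lag_fraction) || length(max_lag_fraction) != 1 ||
      max_lag_fraction <= 0 || max_lag_fraction > 1) {
    stop("`max_lag_fraction` must be in (0, 1]", call. = FALSE)
  }
  n <- length(traj$x)
  m_max <- floor(max_lag_fraction * (n - 1))
  if (m_max < 1) stop("no representable lags inside the requested range", call. = FALSE)
  lags <- seq_len(m_max)
  vals <- vapply(lags, function(m) msd_at_lag(traj, m), 0)
  structure(
    data.frame(lag = lags * traj$settings$frame_interval, msd = vals,
               n_pairs = n - lags),
    class = c("msd_curve", "data.frame"),
    track_id = traj$track_id,
    settings = traj$settings
  )
}

#' Fit a power law to an MSD curve
#'
#' Fits `MSD(tau) = b * tau^alpha` by least squares of `log(msd)` on
#' `log(lag)`. `alpha` is the MSD exponent: ~1 for diffusion, 2 for purely
#' directional transport, below 1 for tethered/confined motion or
#' localization noise. Zero-valued lags are excluded (their log is
#' undefined); if fewer than 3 positive lags remain the fit is reported as
#' `degenerate` with `alpha` and `b` undefined rather than silently coerced.
#'
#' @param msd An `msd_curve` from [compute_msd()].
#' @param weighting `"none"` (default, unweighted) or `"npairs"` (weight
#'   each lag by its displacement-pair count).
#' @return A list of class `power_law_fit`: `b`, `alpha`, `fit_lag_range`,
#'   `n_lags`, `residual` (residual standard deviation on the log scale) and
#'   `status` (`"ok"` or `"degenerate"`).
#' @export
fit_power_law <- function(msd, weighting = c("none", "npairs")) {
  if (!inherits(msd, "msd_curve")) stop("expected an `msd_curve`", call. = FALSE)
  weighting <- match.arg(weighting)
  keep <- is.finite(msd$msd) & msd$msd > 0
  if (sum(keep) < 3) {
    return(structure(
      list(b = NA_real_, alpha = NA_real_, fit_lag_range = c(NA_real_, NA_real_),
           n_lags = sum(keep), residual = NA_real_, status = "degenerate",
           track_id = attr(msd, "track_id")),
      class = "power_law_fit"))
  }
  lx <- log(msd$lag[keep])
  ly <- log(msd$msd[keep])
  w <- if (weighting == "npairs") msd$n_pairs[keep] else rep(1, sum(keep))
  mx <- stats::weighted.mean(lx, w)
  my <- stats::weighted.mean(ly, w)
  slope <- sum(w * (lx - mx) * (ly - my)) / sum(w * (lx - mx)^2)
  intercept <- my - slope * mx
  res <- ly - (intercept + slope * lx)
  structure(
    list(b = exp(intercept), alpha = slope,
         fit_lag_range = range(msd$lag[keep]), n_lags = sum(keep),
         residual = sqrt(sum(w * res^2) / sum(w)), status = "ok",
         track_id = attr(msd, "track_id")),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (x$status == "degenerate") {
    cat("Power-law fit: degenerate (fewer than 3 positive MSD lags)\n")
  } else {
    cat(sprintf("Power-law fit: MSD = %.4g * tau^%.4g over lags [%g, %g] s\n",
                x$b, x$alpha, x$fit_lag_range[1], x$fit_lag_range[2]))
  }
  invisible(x)
}

#' Distribution of fitted MSD exponents over a population
#'
#' Fits the power law per trajectory, drops degenerate fits (counting them)
#' and returns the alpha sample with its empirical cumulative distribution
#' function.
#'
#' @param trajs Non-empty list of [trajectory()] objects.
#' @param label Population label carried into the result.
#' @param max_lag_fraction,weighting Passed to [compute_msd()] and
#'   [fit_power_law()].
#' @return A list of class `alpha_distribution`: `label`, `alphas`, `cdf`
#'   (a [stats::ecdf()]), `n_degenerate`, and a `fits` data frame
#'   (`track_id`, `b`, `alpha`, `tau_min`, `tau_max`, `residual`, `status`).
#' @export
alpha_distribution <- function(trajs, label = "population",
                               max_lag_fraction = 0.25,
                               weighting = c("none", "npairs")) {
  if (!is.list(trajs) || length(trajs) == 0) {
    stop("`trajs` must be a non-empty list of trajectories", call. = FALSE)
  }
  weighting <- match.arg(weighting)
  fits <- lapply(trajs, function(tr) {
    fit_power_law(compute_msd(tr, max_lag_fraction), weighting)
  })
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(track_id = if (is.null(f$track_id)) NA_character_ else f$track_id,
               b = f$b, alpha = f$alpha, tau_min = f$fit_lag_range[1],
               tau_max = f$fit_lag_range[2], residual = f$residual,
               status = f$status, stringsAsFactors = FALSE)
  }))
  alphas <- tab$alpha[tab$status == "ok"]
  if (length(alphas) == 0) {
    stop("all trajectories produced degenerate fits", call. = FALSE)
  }
  structure(
    list(label = label, alphas = alphas, cdf = stats::ecdf(alphas),
         n_degenerate = sum(tab$status == "degenerate"), fits = tab),
    class = "alpha_distribution")
}

#' @export
print.alpha_distribution <- function(x, ...) {
  cat(sprintf("Alpha distribution '%s': n = %d (degenerate excluded: %d)\n",
              x$label, length(x$alphas), x$n_degenerate))
  cat(sprintf("  mean %.3f, median %.3f, sd %.3f\n",
              mean(x$alphas), stats::median(x$alphas), stats::sd(x$alphas)))
  invisible(x)
}

#' Compare two alpha distributions
#'
#' Two-sided unpaired rank-sum (Mann-Whitney/Wilcoxon) comparison of the
#' fitted exponent samples of two populations, with the direction of the
#' median shift.
#'
#' @param dist_a,dist_b [alpha_distribution()] objects (or plain numeric
#'   alpha vectors).
#' @return A `group_comparison` (see [compare_groups()]) with an added
#'   `shift` field: `"right"` if the second sample's median alpha exceeds
#'   the first's, `"left"` if lower, `"none"` otherwise.
#' @export
compare_alpha <- function(dist_a, dist_b) {
  get <- function(d, default) {
    if (inherits(d, "alpha_distribution")) list(a = d$alphas, l = d$label)
    else list(a = as.numeric(d), l = default)
  }
  A <- get(dist_a, "A"); B <- get(dist_b, "B")
  cmp <- compare_groups(A$a, B$a, test = "mann_whitney", labels = c(A$l, B$l))
  md <- stats::median(B$a) - stats::median(A$a)
  cmp$shift <- if (md > 0) "right" else if (md < 0) "left" else "none"
  cmp
}
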