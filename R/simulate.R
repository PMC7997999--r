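#' Simulation parameters for a synthetic trajectory
#'
#' Describes one elementary motion process: free diffusion (`brownian`),
#' constant-velocity transport (`directional`), their superposition
#' (`brownian_drift`), elastic tethering to a fixed point modelled as an
#' Ornstein-Uhlenbeck process (`tethered`), or diffusion with reflecting
#' confinement in a square box (`confined`). Localization noise and pixel
#' quantization are layered on top of the ideal process, in that order,
#' mirroring the physical imaging chain.
#'
#' @param process One of `"brownian"`, `"directional"`, `"brownian_drift"`,
#'   `"tethered"`, `"confined"`.
#' @param D Diffusion coefficient, um^2/s (>= 0).
#' @param V Transport speed, um/s (>= 0).
#' @param heading Transport direction, radians.
#' @param k Tether relaxation rate, 1/s (> 0 for `tethered`).
#' @param box_side Side of the confining square, microns (> 0 for `confined`).
#' @param noise_sigma Per-coordinate Gaussian localization noise, microns (>= 0).
#' @param origin Starting position `c(x, y)`, microns. For `tethered` this is
#'   also the tether point; for `confined` the box centre.
#' @param seed Optional integer seed; when set, simulation is reproducible.
#'
#' @return An object of class `sim_params`.
#' @seealso [simulate_trajectory()], [generate_population()]
#' @export
sim_params <- function(process = c("brownian", "directional", "brownian_drift",
                                   "tethered", "confined"),
                       D = 0, V = 0, heading = 0, k = 0, box_side = NULL,
                       noise_sigma = 0, origin = c(0, 0), seed = NULL) {
  process <- match.arg(process)
  num1 <- function(v, nm, min = -Inf, strict = FALSE) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) ||
        (strict && v <= min) || (!strict && v < min)) {
      stop(sprintf("`%s` must be a single finite number %s %g", nm,
                   if (strict) ">" else ">=", min), call. = FALSE)
    }
    as.numeric(v)
  }
  D <- num1(D, "D", 0)
  V <- num1(V, "V", 0)
  heading <- num1(heading, "heading")
  k <- num1(k, "k", 0)
  noise_sigma <- num1(noise_sigma, "noise_sigma", 0)
  if (!is.null(box_side)) box_side <- num1(box_side, "box_side", 0, strict = TRUE)
  if (process == "tethered" && k <= 0) {
    stop("tethered process requires relaxation rate `k` > 0", call. = FALSE)
  }
  if (process == "confined" && is.null(box_side)) {
    stop("confined process requires `box_side`", call. = FALSE)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 2 || !all(is.finite(origin))) {
    stop("`origin` must be a finite (x, y) pair", call. = FALSE)
  }
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
      stop("`seed` must be a single integer", call. = FALSE)
    }
    seed <- as.integer(seed)
  }
  structure(
    list(process = process, D = D, V = V, heading = heading, k = k,
         box_side = box_side, noise_sigma = noise_sigma, origin = origin,
         seed = seed),
    class = "sim_params"
  )
}

is_sim_params <- function(x) inherits(x, "sim_params")

# Deterministic child seed derivation: one root seed, per-trajectory seeds by
# index. Constants small enough that arithmetic stays exact in doubles.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed %% 2147483647L) * 69069 + index * 10007) %% 2147483646) + 1L
}

apply_seed <- function(params) {
  if (!is.null(params$seed)) set.seed(params$seed)
  invisible(NULL)
}

finish_trajectory <- function(x, y, params, settings, track_id) {
  traj <- trajectory(track_id, x, y, settings, provenance = params)
  if (params$noise_sigma > 0) {
    # continue the already-seeded stream so one seed fixes the whole chain
    traj <- add_localization_noise(traj, params$noise_sigma)
  }
  traj
}

#' Simulate a free 2D Brownian trajectory
#'
#' Positions follow exact Gaussian increments: each coordinate advances by
#' `N(0, 2 D dt)` per frame, so the ensemble obeys the 2D diffusion law
#' `MSD(tau) = 4 D tau` at every lag with no discretization bias.
#'
#' @param params A [sim_params()] with `process = "brownian"`.
#' @param settings An [acq_settings()].
#' @param track_id Identifier for the generated trajectory.
#' @return A [trajectory()].
#' @examples
#' tr <- simulate_brownian(sim_params("brownian", D = 0.01, seed = 1))
#' @export
simulate_brownian <- function(params, settings = acq_settings(), track_id = "sim") {
  stopifnot(is_sim_params(params), is_acq_settings(settings))
  if (params$process != "brownian") stop("`params$process` must be 'brownian'", call. = FALSE)
  apply_seed(params)
  n <- settings$n_frames
  s <- sqrt(2 * params$D * settings$frame_interval)
  x <- params$origin[1] + cumsum(c(0, stats::rnorm(n - 1, 0, s)))
  y <- params$origin[2] + cumsum(c(0, stats::rnorm(n - 1, 0, s)))
  finish_trajectory(x, y, params, settings, track_id)
}

#' Simulate a constant-velocity (purely directional) trajectory
#'
#' Positions advance deterministically at speed `V` along `heading`, so the
#' noiseless mean-square displacement is exactly `V^2 tau^2`.
#'
#' @inheritParams simulate_brownian
#' @return A [trajectory()].
#' @export
simulate_directional <- function(params, settings = acq_settings(), track_id = "sim") {
  stopifnot(is_sim_params(params), is_acq_settings(settings))
  if (params$process != "directional") stop("`params$process` must be 'directional'", call. = FALSE)
  apply_seed(params)
  t <- (seq_len(settings$n_frames) - 1) * settings$frame_interval
  x <- params$origin[1] + params$V * t * cos(params$heading)
  y <- params$origin[2] + params$V * t * sin(params$heading)
  finish_trajectory(x, y, params, settings, track_id)
}

#' Simulate diffusion superposed with constant drift
#'
#' Brownian increments plus a deterministic drift `V` along `heading`;
#' ensemble MSD is `4 D tau + V^2 tau^2`.
#'
#' @inheritParams simulate_brownian
#' @return A [trajectory()].
#' @export
simulate_brownian_drift <- function(params, settings = acq_settings(), track_id = "sim") {
  stopifnot(is_sim_params(params), is_acq_settings(settings))
  if (params$process != "brownian_drift") {
    stop("`params$process` must be 'brownian_drift'", call. = FALSE)
  }
  apply_seed(params)
  n <- settings$n_frames
  dt <- settings$frame_interval
  s <- sqrt(2 * params$D * dt)
  t <- (seq_len(n) - 1) * dt
  x <- params$origin[1] + cumsum(c(0, stats::rnorm(n - 1, 0, s))) +
    params$V * t * cos(params$heading)
  y <- params$origin[2] + cumsum(c(0, stats::rnorm(n - 1, 0, s))) +
    params$V * t * sin(params$heading)
  finish_trajectory(x, y, params, settings, track_id)
}

#' Simulate elastic tethering to a fixed point (Ornstein-Uhlenbeck)
#'
#' Each coordinate follows the exact discrete OU update about the tether
#' point `origin`: `x[i+1] = mu + (x[i] - mu) exp(-k dt) + N(0, (D/k)(1 -
#' exp(-2 k dt)))`. The stationary per-coordinate variance is `D/k`, so the
#' long-lag 2D MSD plateaus at `4 D / k`. Exact updates (rather than Euler
#' steps) keep closed-form checks free of step-size bias.
#'
#' @inheritParams simulate_brownian
#' @return A [trajectory()].
#' @export
simulate_tethered <- function(params, settings = acq_settings(), track_id = "sim") {
  stopifnot(is_sim_params(params), is_acq_settings(settings))
  if (params$process != "tethered") stop("`params$process` must be 'tethered'", call. = FALSE)
  if (params$k <= 0) stop("tethered process requires `k` > 0", call. = FALSE)
  apply_seed(params)
  n <- settings$n_frames
  a <- exp(-params$k * settings$frame_interval)
  s <- sqrt((params$D / params$k) * (1 - a^2))
  # recursive AR(1) filter implements the exact OU recursion, started at the
  # tether point
  ou <- function() {
    if (params$D == 0) return(rep(0, n))
    e <- stats::rnorm(n - 1, 0, s)
    c(0, as.numeric(stats::filter(e, a, method = "recursive")))
  }
  x <- params$origin[1] + ou()
  y <- params$origin[2] + ou()
  finish_trajectory(x, y, params, settings, track_id)
}

# Fold a free coordinate into [lo, hi] by repeated mirror reflection
# (method of images); preserves the equilibrium uniform distribution.
reflect_fold <- function(z, lo, hi) {
  L <- hi - lo
  u <- (z - lo) %% (2 * L)
  lo + ifelse(u > L, 2 * L - u, u)
}

#' Simulate diffusion confined to a square box with reflecting walls
#'
#' Free Brownian paths are folded into the axis-aligned square of side
#' `box_side` centred on `origin` by mirror reflection applied per axis,
#' which realizes reflected Brownian motion exactly in distribution. The
#' long-lag 2D MSD plateaus at `box_side^2 / 3` (twice the per-coordinate
#' uniform variance `L^2/12`, at both endpoints).
#'
#' @inheritParams simulate_brownian
#' @return A [trajectory()]; every position lies inside the closed square.
#' @export
simulate_confined <- function(params, settings = acq_settings(), track_id = "sim") {
  stopifnot(is_sim_params(params), is_acq_settings(settings))
  if (params$process != "confined") stop("`params$process` must be 'confined'", call. = FALSE)
  if (is.null(params$box_side) || params$box_side <= 0) {
    stop("confined process requires `box_side` > 0", call. = FALSE)
  }
  half <- params$box_side / 2
  # origin is both start and box centre; starting outside the box is invalid
  lo_x <- params$origin[1] - half; hi_x <- params$origin[1] + half
  lo_y <- params$origin[2] - half; hi_y <- params$origin[2] + half
  apply_seed(params)
  n <- settings$n_frames
  s <- sqrt(2 * params$D * settings$frame_interval)
  xf <- params$origin[1] + cumsum(c(0, stats::rnorm(n - 1, 0, s)))
  yf <- params$origin[2] + cumsum(c(0, stats::rnorm(n - 1, 0, s)))
  finish_trajectory(reflect_fold(xf, lo_x, hi_x), reflect_fold(yf, lo_y, hi_y),
                    params, settings, track_id)
}

#' Simulate one trajectory from its parameter object
#'
#' Dispatches on `params$process` to the matching generator.
#'
#' @inheritParams simulate_brownian
#' @param params A [sim_params()] of any process kind.
#' @return A [trajectory()].
#' @export
simulate_trajectory <- function(params, settings = acq_settings(), track_id = "sim") {
  stopifnot(is_sim_params(params))
  switch(params$process,
    brownian = simulate_brownian(params, settings, track_id),
    directional = simulate_directional(params, settings, track_id),
    brownian_drift = simulate_brownian_drift(params, settings, track_id),
    tethered = simulate_tethered(params, settings, track_id),
    confined = simulate_confined(params, settings, track_id)
  )
}

#' Add Gaussian localization noise to a trajectory
#'
#' Adds independent `N(0, noise_sigma^2)` to each coordinate of each frame,
#' emulating tracking/analysis noise. In 2D this offsets the ensemble MSD by
#' a constant `4 noise_sigma^2` at every positive lag. The input trajectory
#' is not modified.
#'
#' @param traj A [trajectory()].
#' @param noise_sigma Per-coordinate noise standard deviation, microns (>= 0).
#' @param seed Optional integer seed for the noise draw.
#' @return A new [trajectory()].
#' @export
add_localization_noise <- function(traj, noise_sigma, seed = NULL) {
  assert_trajectory(traj, min_frames = 1L)
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1 ||
      !is.finite(noise_sigma) || noise_sigma < 0) {
    stop("`noise_sigma` must be a single number >= 0", call. = FALSE)
  }
  if (noise_sigma == 0) return(traj)
  if (!is.null(seed)) set.seed(seed)
  n <- length(traj$x)
  traj$x <- traj$x + stats::rnorm(n, 0, noise_sigma)
  traj$y <- traj$y + stats::rnorm(n, 0, noise_sigma)
  traj
}

#' Quantize trajectory coordinates to the pixel grid
#'
#' Rounds each coordinate to the nearest multiple of the pixel size, emulating
#' what a pixel-resolution tracking plugin records. Idempotent; the maximum
#' per-coordinate displacement is half a pixel.
#'
#' @param traj A [trajectory()].
#' @param pixel_size Grid pitch, microns; defaults to the trajectory's
#'   acquisition pixel size.
#' @return A new [trajectory()] on the pixel grid.
#' @export
quantize_to_pixels <- function(traj, pixel_size = NULL) {
  assert_trajectory(traj, min_frames = 1L)
  if (is.null(pixel_size)) pixel_size <- traj$settings$pixel_size
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  }
  traj$x <- round(traj$x / pixel_size) * pixel_size
  traj$y <- round(traj$y / pixel_size) * pixel_size
  traj
}

#' Generate a mixed population of synthetic trajectories
#'
#' Takes a population specification - a list of components, each a list with
#' a [sim_params()] `params` and a `count` - and generates the requested
#' numbers of trajectories. One root seed drives the whole population:
#' per-trajectory child seeds are derived deterministically by index, and the
#' final ordering is a seeded shuffle, so regeneration with the same spec and
#' seed is bit-identical. Each trajectory carries its generating parameters
#' as provenance, enabling classification-recovery checks.
#'
#' @param spec List of components `list(params = sim_params(...), count = n)`.
#' @param settings An [acq_settings()].
#' @param seed Root integer seed.
#' @param id_prefix Prefix for generated track ids.
#' @return A list of [trajectory()] objects.
#' @examples
#' pop <- generate_population(
#'   list(list(params = sim_params("brownian", D = 0.005), count = 3)),
#'   seed = 7)
#' @export
generate_population <- function(spec, settings = acq_settings(), seed = 1,
                                id_prefix = "trk") {
  if (!is.list(spec) || length(spec) == 0) {
    stop("`spec` must be a non-empty list of (params, count) components", call. = FALSE)
  }
  counts <- vapply(spec, function(comp) {
    if (is.null(comp$params) || !is_sim_params(comp$params)) {
      stop("each spec component needs a `params` sim_params object", call. = FALSE)
    }
    cnt <- comp$count
    if (is.null(cnt)) cnt <- 75
    if (!is.numeric(cnt) || length(cnt) != 1 || cnt < 0 || cnt != round(cnt)) {
      stop("each spec component needs an integer `count` >= 0", call. = FALSE)
    }
    as.integer(cnt)
  }, integer(1))
  total <- sum(counts)
  if (total == 0) return(list())
  trajs <- vector("list", total)
  idx <- 0L
  for (ci in seq_along(spec)) {
    for (j in seq_len(counts[ci])) {
      idx <- idx + 1L
      p <- spec[[ci]]$params
      p$seed <- child_seed(seed, idx)
      trajs[[idx]] <- simulate_trajectory(
        p, settings, sprintf("%s%04d", id_prefix, idx))
    }
  }
  set.seed(child_seed(seed, 0L))
  trajs[sample.int(total)]
}

#' Generate a synthetic cell geometry
#'
#' Produces a nucleus outline and a cell outline, circular by default, as a
#' stand-in for segmented DAPI/brightfield outlines. The nucleus centre may
#' be offset from the cell centre; an offset large enough for the perinuclear
#' band to cross the cell boundary exercises the out-of-cell area
#' subtraction. Setting `n_vertices` emits seeded, radially jittered polygons
#' instead of analytic circles.
#'
#' @param nucleus_radius,cell_radius Radii, microns (> 0).
#' @param nucleus_offset Distance of the nucleus centre from the cell centre
#'   along the x axis, microns.
#' @param band_width Perinuclear band width, microns (default 2).
#' @param n_vertices If non-NULL, emit polygons with this many vertices.
#' @param jitter Relative radial jitter for polygonal outlines (e.g. 0.05).
#' @param seed Seed for the jitter draw.
#' @return A [cell_geometry()].
#' @export
generate_cell_geometry <- function(nucleus_radius, cell_radius,
                                   nucleus_offset = 0, band_width = 2,
                                   n_vertices = NULL, jitter = 0, seed = NULL) {
  if (!is.numeric(nucleus_radius) || nucleus_radius <= 0 ||
      !is.numeric(cell_radius) || cell_radius <= 0) {
    stop("radii must be positive", call. = FALSE)
  }
  if (nucleus_offset >= cell_radius + nucleus_radius) {
    warning("nucleus outline is disjoint from the cell outline", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mk <- function(center, radius) {
    if (is.null(n_vertices)) return(circle_outline(center, radius))
    th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    r <- radius * (1 + if (jitter > 0) stats::runif(n_vertices, -jitter, jitter) else 0)
    polygon_outline(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
  }
  cell_geometry(
    nucleus = mk(c(nucleus_offset, 0), nucleus_radius),
    cell = mk(c(0, 0), cell_radius),
    band_width = band_width
  )
}
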