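test_that("acquisition settings validate and derive duration", {
  s <- acq_settings()
  expect_equal(s$duration, 300)
  expect_equal(s$n_frames, 601L)
  expect_error(acq_settings(frame_interval = 0), "frame_interval")
  expect_error(acq_settings(n_frames = 1), "n_frames")
  expect_error(acq_settings(pixel_size = -1), "pixel_size")
})

test_that("generators are deterministic under a fixed seed", {
  s <- acq_settings(n_frames = 101)
  for (p in list(sim_params("brownian", D = 0.01, seed = 5),
                 sim_params("tethered", D = 0.01, k = 1, seed = 5),
                 sim_params("confined", D = 0.01, box_side = 1, seed = 5),
                 sim_params("brownian_drift", D = 0.01, V = 0.05, seed = 5),
                 sim_params("brownian", D = 0.01, noise_sigma = 0.05, seed = 5))) {
    t1 <- simulate_trajectory(p, s)
    t2 <- simulate_trajectory(p, s)
    expect_identical(t1$x, t2$x)
    expect_identical(t1$y, t2$y)
  }
})

test_that("zero-intensity processes are stationary at the origin", {
  s <- acq_settings()
  b <- simulate_brownian(sim_params("brownian", D = 0, origin = c(1, 2), seed = 1), s)
  expect_true(all(b$x == 1) && all(b$y == 2))
  expect_equal(length(b$x), 601L)
  d <- simulate_directional(sim_params("directional", V = 0, seed = 1), s)
  expect_true(all(d$x == 0) && all(d$y == 0))
  te <- simulate_tethered(sim_params("tethered", D = 0, k = 2, origin = c(3, 4), seed = 1), s)
  expect_true(all(te$x == 3) && all(te$y == 4))
})

test_that("parameter validation rejects invalid processes", {
  expect_error(sim_params("brownian", D = -1), "D")
  expect_error(sim_params("tethered", D = 0.01, k = 0), "k")
  expect_error(sim_params("confined", D = 0.01), "box_side")
  expect_error(sim_params("confined", D = 0.01, box_side = -2), "box_side")
  expect_error(add_localization_noise(
    simulate_directional(sim_params("directional", V = 0)), -0.1), "noise_sigma")
})

test_that("directional trajectories follow the constant-velocity law exactly", {
  s <- acq_settings()
  tr <- simulate_directional(sim_params("directional", V = 0.04, heading = 0), s)
  expect_equal(tr$x[601] - tr$x[1], 0.04 * 300)
  expect_equal(tr$y, rep(0, 601))
  msd <- compute_msd(tr, max_lag_fraction = 0.25)
  expect_equal(msd$msd, 0.04^2 * msd$lag^2, tolerance = 1e-12)
})

test_that("Brownian ensembles obey MSD = 4 D tau within Monte-Carlo error", {
  s <- acq_settings(n_frames = 121)
  D <- 0.01
  set.seed(42)
  vals <- vapply(1:800, function(i) {
    tr <- simulate_brownian(sim_params("brownian", D = D, seed = 42000 + i), s)
    vapply(c(2L, 10L, 30L), function(m) {
      n <- length(tr$x)
      mean((tr$x[(m + 1):n] - tr$x[1:(n - m)])^2 +
             (tr$y[(m + 1):n] - tr$y[1:(n - m)])^2)
    }, 0)
  }, numeric(3))
  for (k in 1:3) {
    tau <- c(2, 10, 30)[k] * 0.5
    mu <- mean(vals[k, ])
    se <- sd(vals[k, ]) / sqrt(ncol(vals))
    expect_lt(abs(mu - 4 * D * tau), 3 * se)
  }
})

test_that("tethered motion plateaus at 4 D / k and decorrelates for large k", {
  s <- acq_settings(n_frames = 301)
  D <- 0.01; k <- 0.5
  set.seed(43)
  plateau <- vapply(1:400, function(i) {
    tr <- simulate_tethered(sim_params("tethered", D = D, k = k, seed = 50000 + i), s)
    m <- 100L; n <- 301L
    mean((tr$x[(m + 1):n] - tr$x[1:(n - m)])^2 +
           (tr$y[(m + 1):n] - tr$y[1:(n - m)])^2)
  }, 0)
  se <- sd(plateau) / sqrt(length(plateau))
  expect_lt(abs(mean(plateau) - 4 * D / k), 4 * se)

  # kdt >> 1: successive positions nearly independent, MSD flat, alpha ~ 0
  tr <- simulate_tethered(sim_params("tethered", D = 0.01, k = 50, seed = 9), s)
  fit <- fit_power_law(compute_msd(tr))
  expect_lt(abs(fit$alpha), 0.1)
})

test_that("small k dt limit reproduces free Brownian increment variance", {
  s <- acq_settings(n_frames = 2001, frame_interval = 0.5)
  D <- 0.01; k <- 1e-4   # k dt = 5e-5
  tr <- simulate_tethered(sim_params("tethered", D = D, k = k, seed = 77), s)
  v <- var(diff(tr$x))
  # first-order OU increment variance ~ 2 D dt
  expect_lt(abs(v - 2 * D * 0.5) / (2 * D * 0.5), 0.15)
})

test_that("confined motion stays in the box and plateaus at box_side^2 / 3", {
  s <- acq_settings(n_frames = 301)
  L <- 0.5
  set.seed(44)
  plateau <- vapply(1:400, function(i) {
    tr <- simulate_confined(
      sim_params("confined", D = 0.01, box_side = L, origin = c(2, -1),
                 seed = 60000 + i), s)
    expect_true(all(tr$x >= 2 - L / 2 - 1e-12 & tr$x <= 2 + L / 2 + 1e-12))
    expect_true(all(tr$y >= -1 - L / 2 - 1e-12 & tr$y <= -1 + L / 2 + 1e-12))
    m <- 100L; n <- 301L
    mean((tr$x[(m + 1):n] - tr$x[1:(n - m)])^2 +
           (tr$y[(m + 1):n] - tr$y[1:(n - m)])^2)
  }, 0)
  se <- sd(plateau) / sqrt(length(plateau))
  expect_lt(abs(mean(plateau) - L^2 / 3), 4 * se)
})

test_that("a huge box reproduces free diffusion over the observed lags", {
  s <- acq_settings(n_frames = 301)
  pc <- sim_params("confined", D = 0.01, box_side = 1000, seed = 3)
  pf <- sim_params("brownian", D = 0.01, seed = 3)
  expect_equal(simulate_confined(pc, s)$x, simulate_brownian(pf, s)$x)
})

test_that("localization noise adds 4 sigma^2 to the ensemble MSD", {
  s <- acq_settings(n_frames = 201)
  sigma <- 0.05
  base <- simulate_directional(sim_params("directional", V = 0), s)
  set.seed(45)
  vals <- vapply(1:300, function(i) {
    tr <- add_localization_noise(base, sigma, seed = 70000 + i)
    m <- 5L; n <- 201L
    mean((tr$x[(m + 1):n] - tr$x[1:(n - m)])^2 +
           (tr$y[(m + 1):n] - tr$y[1:(n - m)])^2)
  }, 0)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 4 * sigma^2), 4 * se)
  # sigma = 0 leaves the trajectory untouched
  expect_identical(add_localization_noise(base, 0), base)
})

test_that("noise layering is additive in ensemble MSD for Brownian motion", {
  s <- acq_settings(n_frames = 201)
  D <- 0.005; sigma <- 0.04; m <- 4L; n <- 201L
  msd_at <- function(tr) mean((tr$x[(m + 1):n] - tr$x[1:(n - m)])^2 +
                                (tr$y[(m + 1):n] - tr$y[1:(n - m)])^2)
  set.seed(46)
  noisy <- vapply(1:400, function(i) {
    msd_at(simulate_brownian(
      sim_params("brownian", D = D, noise_sigma = sigma, seed = 80000 + i), s))
  }, 0)
  se <- sd(noisy) / sqrt(length(noisy))
  expect_lt(abs(mean(noisy) - (4 * D * m * 0.5 + 4 * sigma^2)), 4 * se)
})

test_that("pixel quantization rounds to the nearest pixel and is idempotent", {
  tr <- make_traj(c(0.07, 0.09, 0.31), c(0.09, -0.09, 0.0))
  q <- quantize_to_pixels(tr)
  expect_equal(q$x, c(0, 0.16, 0.32))
  expect_equal(q$y, c(0.16, -0.16, 0))
  expect_equal(quantize_to_pixels(q)$x, q$x)
  set.seed(8)
  tr2 <- make_traj(runif(200, -5, 5), runif(200, -5, 5))
  q2 <- quantize_to_pixels(tr2)
  expect_lte(max(abs(q2$x - tr2$x)), 0.08 + 1e-12)
  expect_lte(max(abs(q2$y - tr2$y)), 0.08 + 1e-12)
})

test_that("population generation honours counts, labels and the root seed", {
  s <- acq_settings(n_frames = 11)
  spec <- list(
    list(params = sim_params("brownian", D = 0.005), count = 60),
    list(params = sim_params("directional", V = 0.05), count = 15))
  pop1 <- generate_population(spec, s, seed = 31)
  pop2 <- generate_population(spec, s, seed = 31)
  expect_length(pop1, 75)
  procs <- vapply(pop1, function(tr) tr$provenance$process, "")
  expect_equal(sum(procs == "brownian"), 60)
  expect_equal(sum(procs == "directional"), 15)
  expect_identical(lapply(pop1, `[[`, "x"), lapply(pop2, `[[`, "x"))
  # shuffling is seeded: a different root seed gives a different arrangement
  pop3 <- generate_population(spec, s, seed = 32)
  expect_false(identical(lapply(pop1, `[[`, "x"), lapply(pop3, `[[`, "x")))
  expect_error(generate_population(list(), s, seed = 1), "non-empty")
})

test_that("synthetic cell geometries respect radii and reproducibility", {
  g <- generate_cell_geometry(5, 15)
  expect_s3_class(g, "cell_geometry")
  expect_equal(g$nucleus$radius, 5)
  # nucleus protruding far enough is flagged
  expect_warning(generate_cell_geometry(5, 10, nucleus_offset = 20), "disjoint")
  expect_error(generate_cell_geometry(-1, 10), "positive")
  gp1 <- generate_cell_geometry(5, 15, n_vertices = 64, jitter = 0.05, seed = 2)
  gp2 <- generate_cell_geometry(5, 15, n_vertices = 64, jitter = 0.05, seed = 2)
  expect_identical(gp1$nucleus$vertices, gp2$nucleus$vertices)
})
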