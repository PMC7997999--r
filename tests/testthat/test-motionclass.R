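ref_frontiers <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- calibrate_frontiers(n_reference = 1500, seed = 1234)
    }
    memo
  }
})

test_that("second moments reuse the time-averaged MSD at the two lags", {
  stationary <- make_traj(rep(0, 601), rep(0, 601))
  mp <- compute_moments(stationary)
  expect_equal(c(mp$mu2S, mp$mu2L), c(0, 0))
  line <- simulate_directional(sim_params("directional", V = 0.03), acq_settings())
  mpl <- compute_moments(line, tau_S = 5, tau_L = 40)
  expect_equal(mpl$mu2L / mpl$mu2S, (40 / 5)^2, tolerance = 1e-10)
  expect_equal(mpl$mu2S, bf_msd_at_lag(line$x, line$y, 10), tolerance = 1e-10)
  expect_error(compute_moments(line, tau_S = 5.3, tau_L = 40), "multiple")
  expect_error(compute_moments(line, tau_S = 40, tau_L = 5), "smaller")
})

test_that("Brownian moment ratio approaches tau_L / tau_S in the ensemble", {
  s <- acq_settings(n_frames = 301)
  pop <- generate_population(
    list(list(params = sim_params("brownian", D = 0.01), count = 400)),
    s, seed = 55)
  mom <- population_moments(pop, 5, 40)
  expect_equal(mean(mom$mu2L) / mean(mom$mu2S), 8, tolerance = 0.1)
})

test_that("frontier calibration matches its quantile definition and is D-invariant", {
  fr <- ref_frontiers()
  expect_lt(fr$c_low, fr$c_high)
  # recompute the reference cloud: the fraction above c_high is 1 - q_high
  ref <- generate_population(
    list(list(params = sim_params("brownian", D = fr$D), count = fr$n_reference)),
    fr$settings, seed = fr$seed, id_prefix = "ref")
  s_vals <- population_moments(ref, fr$tau_S, fr$tau_L)$s
  expect_equal(mean(s_vals > fr$c_high), 1 - fr$q_high, tolerance = 2 / fr$n_reference)
  # s is a pivot for Brownian motion: offsets agree across reference D values
  fr_small <- calibrate_frontiers(n_reference = 1500, D = 1e-3, seed = 81)
  fr_large <- calibrate_frontiers(n_reference = 1500, D = 1e-2, seed = 82)
  expect_lt(abs(fr_small$c_high - fr_large$c_high), 0.08)
  expect_lt(abs(fr_small$c_low - fr_large$c_low), 0.05)
  expect_error(calibrate_frontiers(n_reference = 100), "at least 1000")
  expect_error(calibrate_frontiers(q_low = 0.9, q_high = 0.5), "q_low")
})

test_that("classification labels the canonical cases", {
  fr <- ref_frontiers()
  stationary <- make_traj(rep(1, 601), rep(1, 601))
  expect_equal(classify_motion(stationary, fr), "ND")
  line <- simulate_directional(sim_params("directional", V = 0.05), acq_settings())
  # noiseless directional: s = 2 log10(8) = 1.81, far above the Brownian band
  expect_equal(classify_motion(line, fr), "D")
  # a point exactly on the upper frontier is intermediate
  on_line <- structure(list(mu2S = 1, mu2L = 10^fr$c_high, tau_S = 5, tau_L = 40,
                            track_id = "edge"), class = "moment_pair")
  expect_equal(classify_motion(on_line, fr), "intermediate")
  below <- structure(list(mu2S = 1, mu2L = 10^(fr$c_low - 0.01), tau_S = 5,
                          tau_L = 40, track_id = "low"), class = "moment_pair")
  expect_equal(classify_motion(below, fr), "ND")
})

test_that("classification is invariant under uniform spatial rescaling", {
  fr <- ref_frontiers()
  s <- acq_settings(n_frames = 301)
  for (i in 1:20) {
    tr <- simulate_brownian_drift(
      sim_params("brownian_drift", D = 0.005, V = 0.01 * (i %% 4), seed = 4000 + i), s)
    scaled <- trajectory(tr$track_id, 7.3 * tr$x, 7.3 * tr$y, s)
    expect_identical(classify_motion(tr, fr), classify_motion(scaled, fr))
  }
})

test_that("counts partition the population and report the directional range", {
  fr <- ref_frontiers()
  s <- acq_settings()
  pop <- generate_population(
    list(list(params = sim_params("brownian", D = 0.005), count = 60),
         list(params = sim_params("directional", V = 0.1), count = 15)),
    s, seed = 9)
  dc <- count_directional(pop, fr)
  expect_equal(dc$n_D + dc$n_intermediate + dc$n_ND, 75)
  expect_equal(dc$range, c(dc$n_D, dc$n_D + dc$n_intermediate))
  expect_gte(dc$n_D, 15)  # every planted fast directional track classifies D
})

test_that("false-directional rate on held-out Brownian data matches 1 - q_high", {
  fr <- ref_frontiers()
  held <- generate_population(
    list(list(params = sim_params("brownian", D = 0.01), count = 1000)),
    acq_settings(), seed = 777)
  dc <- count_directional(held, fr)
  p_hat <- dc$n_D / dc$n
  # binomial 99.9% band around 0.05 at n = 1000, widened for the sampling
  # variance of the calibrated quantile itself
  expect_gt(p_hat, 0.02)
  expect_lt(p_hat, 0.09)
})

test_that("well-separated mixtures are recovered with high per-class accuracy", {
  fr <- ref_frontiers()
  s <- acq_settings()
  D <- 0.005
  V <- 5 * sqrt(4 * D * 40) / 40   # drift dominating diffusion at tau_L
  mix <- c(
    generate_population(list(list(
      params = sim_params("brownian", D = D), count = 150)), s, seed = 501,
      id_prefix = "b"),
    generate_population(list(list(
      params = sim_params("brownian_drift", D = D, V = V), count = 150)), s,
      seed = 502, id_prefix = "d"))
  truth <- vapply(mix, function(tr) tr$provenance$process, "")
  labels <- vapply(mix, function(tr) classify_motion(tr, fr), "")
  directional_recovery <- mean(labels[truth == "brownian_drift"] == "D")
  brownian_false_d <- mean(labels[truth == "brownian"] == "D")
  expect_gte(directional_recovery, 0.95)
  # held-out Brownian false-D rate stays inside its binomial band around 0.05
  expect_lt(brownian_false_d, 0.11)
})

test_that("probability of a directional label rises with drift speed", {
  fr <- ref_frontiers()
  # trajectory length matched to the calibration reference, so the V = 0
  # false-directional rate sits at its calibrated level
  s <- acq_settings()
  p_D <- vapply(c(0, 0.03, 0.06, 0.12), function(V) {
    pop <- generate_population(list(list(
      params = sim_params("brownian_drift", D = 0.005, V = V), count = 150)),
      s, seed = 600 + round(1000 * V))
    mean(count_directional(pop, fr)$labels == "D")
  }, 0)
  expect_true(all(diff(p_D) >= 0))
  expect_lt(p_D[1], 0.15)
  expect_gt(p_D[4], 0.9)
})
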