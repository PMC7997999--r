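test_that("total and Euclidean distance match hand-computed paths", {
  tr <- make_traj(c(0, 3, 3), c(0, 4, 4))
  expect_equal(total_distance(tr), 5)      # 3-4-5 triangle then a zero step
  expect_equal(euclidean_distance(tr), 5)
  stationary <- make_traj(rep(1, 601), rep(-2, 601))
  expect_equal(total_distance(stationary), 0)
  line <- make_traj(seq(0, by = 0.04, length.out = 601), rep(0, 601))
  expect_equal(total_distance(line), 24, tolerance = 1e-12)
  expect_equal(euclidean_distance(line), total_distance(line), tolerance = 1e-12)
  loop <- make_traj(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(euclidean_distance(loop), 0)
  expect_error(total_distance(make_traj(1, 1)), "at least 2")
})

test_that("average distance and velocity follow the frame-count convention", {
  # total 60.1 um over 601 frames: 0.1 um/frame and 0.2 um/s
  step <- 60.1 / 600
  tr <- make_traj(seq(0, by = step, length.out = 601), rep(0, 601))
  av <- average_distance_and_velocity(tr)
  expect_equal(av$average_distance, 0.1, tolerance = 1e-12)
  expect_equal(av$average_velocity, 0.2, tolerance = 1e-12)
  # algebraic identity of the definition
  expect_equal(av$average_velocity * 601 * 0.5, total_distance(tr), tolerance = 1e-12)
  # step-count divisor variant
  avs <- average_distance_and_velocity(tr, divisor = "steps")
  expect_equal(avs$average_distance, 60.1 / 600, tolerance = 1e-12)
  z <- average_distance_and_velocity(make_traj(rep(0, 10), rep(0, 10)))
  expect_equal(unlist(z), c(average_distance = 0, average_velocity = 0))
})

test_that("pause fraction counts zero quantized steps", {
  # all frames within one pixel -> everything is a pause
  tr <- make_traj(runif(50, 0, 0.07), runif(50, 0, 0.07))
  expect_equal(pause_fraction(tr), 1)
  # constant two-pixel steps -> never paused
  tr2 <- make_traj(seq(0, by = 0.32, length.out = 50), rep(0, 50))
  expect_equal(pause_fraction(tr2), 0)
  # threshold mode flags sub-pixel raw displacements
  tr3 <- make_traj(c(0, 0.1, 0.4), c(0, 0, 0))
  expect_equal(pause_fraction(tr3, mode = "threshold"), 0.5)
})

test_that("pause fraction agrees with a brute-force census and is high for slow diffusion", {
  s <- acq_settings()
  fractions <- vapply(1:10, function(i) {
    tr <- simulate_brownian(sim_params("brownian", D = 1e-4, seed = 300 + i), s)
    pf <- pause_fraction(tr)
    expect_equal(pf, bf_pause_fraction(tr$x, tr$y, 0.16), tolerance = 1e-12)
    pf
  }, 0)
  expect_gt(mean(fractions), 0.5)
})

test_that("ensemble pause fraction decreases with the diffusion coefficient", {
  s <- acq_settings(n_frames = 301)
  mean_pause <- vapply(c(1e-4, 1e-3, 1e-2), function(D) {
    mean(vapply(1:40, function(i) {
      pause_fraction(simulate_brownian(
        sim_params("brownian", D = D, seed = round(1e5 * D) + i), s))
    }, 0))
  }, 0)
  expect_true(all(diff(mean_pause) < 0))
})

test_that("descriptors are invariant under rigid motions of the trajectory", {
  set.seed(12)
  tr <- make_traj(cumsum(rnorm(100, 0, 0.1)), cumsum(rnorm(100, 0, 0.1)))
  th <- 0.7
  rot <- make_traj(cos(th) * tr$x - sin(th) * tr$y + 3,
                   sin(th) * tr$x + cos(th) * tr$y - 5)
  expect_equal(total_distance(rot), total_distance(tr), tolerance = 1e-12)
  expect_equal(euclidean_distance(rot), euclidean_distance(tr), tolerance = 1e-12)
})

test_that("Euclidean distance never exceeds total distance", {
  for (i in 1:50) {
    set.seed(1000 + i)
    tr <- make_traj(cumsum(rnorm(30, 0, 0.2)), cumsum(rnorm(30, 0, 0.2)))
    expect_lte(euclidean_distance(tr), total_distance(tr) + 1e-12)
    expect_equal(total_distance(tr), bf_total_distance(tr$x, tr$y), tolerance = 1e-12)
  }
})

test_that("radial direction uses net first-to-last radial change with a tolerance", {
  out <- make_traj(c(2, 3.5, 5), c(0, 0, 0))
  expect_equal(radial_direction(out, c(0, 0)), "centrifugal")
  inw <- make_traj(c(5, 3, 2), c(0, 0, 0))
  expect_equal(radial_direction(inw, c(0, 0)), "centripetal")
  loop <- make_traj(c(2, 3, 2), c(0, 1, 0))
  expect_equal(radial_direction(loop, c(0, 0)), "indeterminate")
  # sub-tolerance net change is indeterminate
  tiny <- make_traj(c(2, 2.1), c(0, 0))
  expect_equal(radial_direction(tiny, c(0, 0)), "indeterminate")
  expect_error(radial_direction(out, c(NA, 0)), "finite")
})

test_that("population summaries aggregate correctly", {
  # 6 radially outward, 4 inward lines around a nucleus at the origin
  mk_radial <- function(sign, angle) {
    r <- if (sign > 0) c(2, 4) else c(4, 2)
    make_traj(r * cos(angle), r * sin(angle))
  }
  trajs <- c(lapply(seq(0, 5) * 0.9, function(a) mk_radial(1, a)),
             lapply(seq(0, 3) * 1.1, function(a) mk_radial(-1, a)))
  sm <- summarize_population(trajs, nucleus_center = c(0, 0))
  expect_equal(nrow(sm$tracks), 10)
  expect_equal(sm$aggregate$pct_centrifugal, 60)
  expect_equal(sm$aggregate$pct_centripetal, 40)
  expect_equal(sm$aggregate$mean_total_distance,
               mean(sm$tracks$total_distance), tolerance = 1e-12)
  # identical trajectories have zero dispersion
  same <- replicate(5, make_traj(c(0, 1, 2), c(0, 0, 0)), simplify = FALSE)
  sm2 <- summarize_population(same)
  expect_equal(sm2$aggregate$sd_total_distance, 0)
  expect_error(summarize_population(list()), "non-empty")
})
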