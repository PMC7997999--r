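# Independent brute-force oracles and small fixture builders. These
# deliberately recompute quantities by the most direct route possible
# (double loops, per-step censuses, rejection sampling) so the package's
# vectorized implementations are checked against a separate code path.

make_traj <- function(x, y, frame_interval = 0.5, pixel_size = 0.16,
                      track_id = "fixture") {
  s <- acq_settings(frame_interval = frame_interval, n_frames = max(length(x), 2),
                    pixel_size = pixel_size)
  trajectory(track_id, x, y, s)
}

# Time-averaged MSD at integer frame lag m via an explicit double loop.
bf_msd_at_lag <- function(x, y, m) {
  n <- length(x)
  acc <- 0
  for (t in 1:(n - m)) {
    acc <- acc + (x[t + m] - x[t])^2 + (y[t + m] - y[t])^2
  }
  acc / (n - m)
}

bf_total_distance <- function(x, y) {
  acc <- 0
  for (i in 2:length(x)) {
    acc <- acc + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  }
  acc
}

# Per-step census of identical consecutive pixel-quantized positions.
bf_pause_fraction <- function(x, y, pixel_size) {
  qx <- round(x / pixel_size) * pixel_size
  qy <- round(y / pixel_size) * pixel_size
  paused <- 0
  for (i in 2:length(x)) {
    if (qx[i] == qx[i - 1] && qy[i] == qy[i - 1]) paused <- paused + 1
  }
  paused / (length(x) - 1)
}

# Monte-Carlo rejection-sampling area of the perinuclear band for
# circle/circle geometry, using only direct circle arithmetic.
mc_band_area <- function(nucleus_radius, cell_radius, nucleus_offset,
                         band_width, n = 1e6, seed = 99) {
  set.seed(seed)
  half <- max(cell_radius, nucleus_offset + nucleus_radius + band_width)
  px <- runif(n, -half, half)
  py <- runif(n, -half, half)
  dn <- sqrt((px - nucleus_offset)^2 + py^2)
  dc <- sqrt(px^2 + py^2)
  hit <- dn > nucleus_radius & dn <= nucleus_radius + band_width & dc <= cell_radius
  mean(hit) * (2 * half)^2
}

# Monte-Carlo permutation estimate of the two-sided rank-sum p-value.
mc_ranksum_p <- function(a, b, n_perm = 20000, seed = 7) {
  set.seed(seed)
  na <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  w_null <- replicate(n_perm, sum(r[sample(length(pooled), na)]))
  min(1, 2 * min(mean(w_null <= w_obs + 1e-9), mean(w_null >= w_obs - 1e-9)))
}
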