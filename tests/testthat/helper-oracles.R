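# Independent brute-force oracles used across test files.

# per-axis max-min by explicit looping
oracle_axis_disp <- function(x, y) {
  mx <- -Inf; mn <- Inf; my <- -Inf; ny <- Inf
  for (i in seq_along(x)) {
    if (x[i] > mx) mx <- x[i]; if (x[i] < mn) mn <- x[i]
    if (y[i] > my) my <- y[i]; if (y[i] < ny) ny <- y[i]
  }
  c(mx - mn, my - ny)
}

oracle_path_length <- function(x, y) {
  s <- 0
  for (i in seq_along(x)[-1])
    s <- s + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  s
}

oracle_net_disp <- function(x, y) {
  n <- length(x)
  sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
}

oracle_max_avg_velocity <- function(x, y, frame, dt, window = 3) {
  v <- numeric(0)
  for (i in seq_along(x)[-1])
    v <- c(v, sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2) /
             ((frame[i] - frame[i - 1]) * dt))
  if (length(v) < window) return(NA_real_)
  best <- -Inf
  for (i in 1:(length(v) - window + 1))
    best <- max(best, mean(v[i:(i + window - 1)]))
  best
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact <- function(g1, g2) {
  pooled <- c(g1, g2)
  n1 <- length(g1)
  u_stat <- function(a, b) sum(outer(a, b, ">")) # no ties assumed
  u_obs <- u_stat(g1, g2)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(ii) u_stat(pooled[ii], pooled[-ii]))
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# two-sided Fisher p by enumeration of the conditional table space
oracle_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(xs, r1, n - r1, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random trajectory on a fixed grid of frames
random_track <- function(n, dt = 5, gap_prob = 0) {
  frames <- 0:(n - 1)
  if (gap_prob > 0) frames <- sort(sample(0:(3 * n), n))
  trajectory(frames, stats::rnorm(n, 0, 5), stats::rnorm(n, 0, 5),
             frame_interval_s = dt)
}

# small fast scene for image-based tests
small_scene <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(embryo = ellipsoid_dims(8, 5, 4), pixel_size_um = 0.13,
         n_puncta = 5, n_masses = 0, cloud_sigma_um = 1.5,
         noise_sd = 0, background_level = 0,
         dna_position_um = c(2, 0, 0), seed = seed),
    list(...))
  do.call(scene_config, args)
}
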