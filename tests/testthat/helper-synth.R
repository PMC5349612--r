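# Shared synthetic fixtures and independent oracles.

# two-patch ground-truth profile used across recovery tests
std_profile <- function(baseline = 0.25) {
  adhesion_profile(data.frame(center = c(0.7 * pi, 1.5 * pi),
                              width = c(pi / 2, pi / 3),
                              multiplier = c(4, 3)),
                   baseline_dwell = baseline)
}

# well-separated scatterers (y gaps >= 2 um, away from the projected rim)
std_spots <- function(n = 2) {
  all <- rbind(c(4.5, 1.5, 1.0),
               c(-3.0, -1.5, 3.5),
               c(2.0, 3.6, 3.0),
               c(2.5, -3.8, -2.5))
  all[seq_len(n), , drop = FALSE]
}

# full tracking chain on a simulated movie; returns everything downstream
# tests need. Cached per options key so several test_that blocks in one
# file reuse one simulation.
.chain_cache <- new.env(parent = emptyenv())

run_chain <- function(key, profile, geometry, imaging = imaging_params(),
                      n_cycles = 4.5, seed = 7, detachment_intervals = NULL,
                      detach_speed_factor = 3) {
  if (!is.null(.chain_cache[[key]])) return(.chain_cache[[key]])
  mv <- simulate_rolling_movie(profile, geometry, imaging,
                               n_cycles = n_cycles, seed = seed,
                               detachment_intervals = detachment_intervals,
                               detach_speed_factor = detach_speed_factor)
  det <- segment_movie(mv$movie, imaging$pixel_size)
  tracks <- link_cell_tracks(det, max_jump_um = 8,
                             frame_interval = imaging$frame_interval,
                             min_length = 20)
  track <- tracks[[which.max(vapply(tracks, nrow, 1L))]]
  stack <- crop_cell_frame(mv$movie, track, 9, imaging$pixel_size)
  feats <- detect_spot_features(stack)
  trajs <- link_spot_trajectory(feats, gate_um = 2.5)
  angs <- list()
  for (tj in trajs) {
    R <- try(estimate_radial_distance(tj), silent = TRUE)
    if (!inherits(R, "try-error")) {
      angs[[length(angs) + 1L]] <- reconstruct_angle(tj, R)
    }
  }
  merged <- merge_feature_angles(angs)
  cum <- accumulate_angle(merged$theta_rel)
  tt <- (merged$frame - 1L) * imaging$frame_interval
  xs <- track$x_um[match(merged$frame, track$frame)]
  trac <- traction_classification(cum, xs, geometry$radius)
  out <- list(mv = mv, track = track, stack = stack, feats = feats,
              trajs = trajs, merged = merged, cum = cum, t = tt, x = xs,
              traction = trac)
  .chain_cache[[key]] <- out
  out
}

# RMS deviation between recovered and true cumulative angle (offset-free)
theta_rms <- function(cum, theta_true) {
  off <- mean(cum - theta_true)
  sqrt(mean((cum - theta_true - off)^2))
}

# independent oracle: per-lag-normalized mean-subtracted autocorrelation,
# double loop
acf_oracle <- function(x, max_lag) {
  n <- length(x)
  xc <- x - mean(x)
  c0 <- sum(xc^2) / n
  vapply(0:max_lag, function(k) {
    s <- 0
    for (i in seq_len(n - k)) s <- s + xc[i] * xc[i + k]
    (s / (n - k)) / c0
  }, numeric(1))
}

# independent oracle: rotation angle by grid search over all spot positions
angle_oracle <- function(x_obs, spots_R, spots_phi, grid_n = 7200L) {
  thetas <- (seq_len(grid_n) - 1L) * 2 * pi / grid_n
  pred <- outer(thetas, spots_phi, `+`)
  pred <- sweep(cos(pred), 2, spots_R, `*`)
  cost <- rowSums(sweep(pred, 2, x_obs, `-`)^2)
  thetas[which.min(cost)]
}

# sparse-spot tile generator for illumination-recovery tests
random_spot_tile <- function(shape, n_spots, sigma_px, amplitude = 50) {
  img <- matrix(0, shape[1], shape[2])
  if (n_spots == 0) return(img)
  xs <- runif(n_spots, 1, shape[2])
  ys <- runif(n_spots, 1, shape[1])
  half <- ceiling(4 * sigma_px)
  for (e in seq_len(n_spots)) {
    j0 <- max(1, floor(xs[e] - half)); j1 <- min(shape[2], ceiling(xs[e] + half))
    i0 <- max(1, floor(ys[e] - half)); i1 <- min(shape[1], ceiling(ys[e] + half))
    gx <- exp(-((j0:j1) - xs[e])^2 / (2 * sigma_px^2))
    gy <- exp(-((i0:i1) - ys[e])^2 / (2 * sigma_px^2))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amplitude * outer(gy, gx)
  }
  img
}
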