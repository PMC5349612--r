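px <- 0.53

gauss_frame <- function(ny, nx, centers_px, amp = 100, sigma_px = 1.2,
                        bg = 10) {
  img <- matrix(bg, ny, nx)
  for (k in seq_len(nrow(centers_px))) {
    gx <- exp(-((1:nx) - centers_px[k, 1])^2 / (2 * sigma_px^2))
    gy <- exp(-((1:ny) - centers_px[k, 2])^2 / (2 * sigma_px^2))
    img <- img + amp * outer(gy, gx)
  }
  img
}

test_that("spot detectors localize rendered Gaussians to sub-pixel accuracy", {
  fr <- gauss_frame(31, 31, cbind(15.3, 17.6))
  stack <- array(fr, dim = c(31, 31, 1))
  for (m in c("mser", "log")) {
    feats <- detect_spot_features(stack, method = m, pixel_size = px)
    expect_equal(nrow(feats), 1L)
    expect_lt(abs(feats$x_cm / px + 16 - 15.3), 1)   # within 1 px
    expect_lt(abs(feats$y_cm / px + 16 - 17.6), 1)
  }
  # two spots separated by > 3 sigma are both found
  fr2 <- gauss_frame(31, 31, rbind(c(10, 10), c(22, 20)))
  feats2 <- detect_spot_features(array(fr2, dim = c(31, 31, 1)),
                                 pixel_size = px)
  expect_equal(nrow(feats2), 2L)
})

test_that("pure-noise frames produce almost no false detections", {
  set.seed(99)
  noise <- array(rnorm(31 * 31 * 100, mean = 20, sd = 3),
                 dim = c(31, 31, 100))
  feats <- detect_spot_features(noise, pixel_size = px)
  expect_lt(nrow(feats) / 100, 0.1)
})

test_that("spot linking bridges short gaps and keeps distinct-y spots apart", {
  f <- rep(1:40, each = 2)
  det <- data.frame(frame = f,
                    x_cm = c(rbind(sin(1:40 / 3) * 4, cos(1:40 / 3) * 4)),
                    y_cm = c(rbind(rep(1.5, 40), rep(-1.5, 40))),
                    area_px = 9, score = 1, peak = 100)
  # knock out 2 frames of spot 1 (gap <= 3 bridged)
  det <- det[!(det$frame %in% 20:21 & det$y_cm > 0), ]
  trajs <- link_spot_trajectory(det, gate_um = 2, min_length = 10)
  expect_length(trajs, 2L)
  ys <- vapply(trajs, function(t) mean(t$y_cm), numeric(1))
  expect_equal(sort(ys), c(-1.5, 1.5))
  expect_true(all(vapply(trajs, function(t) length(unique(sign(t$y_cm))),
                         numeric(1)) == 1))
})

test_that("radial distance estimators behave as documented", {
  th <- seq(0, 6 * pi, by = 0.02)
  traj <- data.frame(frame = seq_along(th), x_cm = 5 * cos(th), y_cm = 0)
  expect_equal(as.numeric(estimate_radial_distance(traj, "max")), 5,
               tolerance = 1e-3)
  # under noise the max estimator is biased high; the percentile one is not
  set.seed(5)
  biases <- t(vapply(1:100, function(s) {
    x <- 5 * cos(th) + rnorm(length(th), 0, 0.2)
    tj <- data.frame(frame = seq_along(th), x_cm = x, y_cm = 0)
    c(max = as.numeric(estimate_radial_distance(tj, "max")),
      pct = as.numeric(estimate_radial_distance(tj, "percentile")))
  }, numeric(2)))
  expect_gt(mean(biases[, "max"]), 5)
  expect_lt(abs(mean(biases[, "pct"]) - 5), 0.15)
  # a spot on the rotation axis is rejected
  flat <- data.frame(frame = 1:50, x_cm = rep(0.01, 50), y_cm = 0)
  expect_error(estimate_radial_distance(flat), "rotation axis")
  # a trace without a full oscillation is rejected with a diagnostic
  part <- data.frame(frame = 1:30, x_cm = 5 * cos(seq(0, 2, length.out = 30)),
                     y_cm = 0)
  expect_error(estimate_radial_distance(part), "full oscillation")
})

test_that("arccos mapping, clamping and flagging follow the contract", {
  th <- seq(0.05, 6 * pi, by = 0.1)
  traj <- data.frame(frame = seq_along(th), x_cm = 5 * cos(th), y_cm = 0)
  a <- reconstruct_angle(traj, 5)
  expect_equal(a$alpha[1], acos(cos(0.05)), tolerance = 1e-9)
  expect_false(any(a$clamped))
  # a sample at 1.05 R is clamped and flagged, not dropped
  traj2 <- traj
  traj2$x_cm[10] <- 5 * 1.05
  a2 <- reconstruct_angle(traj2, 5, clamp_tolerance = 0.1)
  expect_true(a2$clamped[10])
  expect_equal(a2$alpha[10], 0)
  # beyond the tolerance the sample is dropped
  traj3 <- traj
  traj3$x_cm[10] <- 5 * 1.2
  a3 <- reconstruct_angle(traj3, 5)
  expect_true(a3$dropped[10])
  expect_true(is.na(a3$theta_rel[10]))
  expect_error(reconstruct_angle(traj, 0), "R must be > 0")
})

test_that("noise-free angle reconstruction matches truth to the 2-degree benchmark", {
  prof <- std_profile()
  dyn <- simulate_rolling_dynamics(prof, cell_geometry(14), n_cycles = 4)
  phi <- 0.8
  traj <- data.frame(frame = seq_len(nrow(dyn)),
                     x_cm = 4.7 * cos(dyn$theta + phi), y_cm = 0)
  a <- reconstruct_angle(traj, 4.7)
  cum <- accumulate_angle(a$theta_rel)
  expect_lt(theta_rms(cum, dyn$theta), 0.035)
  # relative angle matches truth mod 2pi
  d <- (a$theta_rel - (dyn$theta + phi)) %% (2 * pi)
  d <- pmin(d, 2 * pi - d)
  expect_lt(sqrt(mean(d^2)), 0.035)
})

test_that("angle accumulation adds 2*pi at each wrap", {
  saw <- rep(seq(0, 2 * pi - 0.1, by = 0.1), 3)
  cum <- accumulate_angle(saw)
  expect_equal(cum[length(cum)], 4 * pi + max(saw), tolerance = 1e-9)
  expect_equal(floor(cum[length(cum)] / (2 * pi)), 2)  # two full wraps seen
  expect_true(all(diff(cum) >= 0))
  expect_equal(accumulate_angle(1.2), 1.2)
  expect_equal(sum(is.na(accumulate_angle(c(1, NA, 2)))), 1L)
})

test_that("merging feature angles aligns offsets and reduces error", {
  th <- seq(0.03, 8 * pi, by = 0.08)
  base <- wrap_2pi(th)
  tr1 <- data.frame(frame = seq_along(th), theta_rel = base)
  # identical traces merge to themselves
  m0 <- merge_feature_angles(list(tr1, tr1))
  expect_equal(m0$theta_rel, base, tolerance = 1e-7)
  expect_lt(max(m0$sd), 1e-6)
  # constant offset pi/3 adds no variance after alignment
  tr2 <- data.frame(frame = seq_along(th), theta_rel = wrap_2pi(th + pi / 3))
  m1 <- merge_feature_angles(list(tr1, tr2))
  expect_lt(max(m1$sd), 1e-6)
  # three noisy traces merge better than one (Monte-Carlo)
  set.seed(7)
  gains <- vapply(1:50, function(s) {
    noisy <- lapply(c(0, 1, 2), function(off)
      data.frame(frame = seq_along(th),
                 theta_rel = wrap_2pi(th + off + rnorm(length(th), 0, 0.05))))
    mm <- merge_feature_angles(noisy)
    cum_m <- accumulate_angle(mm$theta_rel)
    cum_1 <- accumulate_angle(noisy[[1]]$theta_rel)
    theta_rms(cum_1, th) - theta_rms(cum_m, th)
  }, numeric(1))
  expect_gt(mean(gains > 0), 0.9)
  # irreconcilable traces are excluded
  junk <- data.frame(frame = seq_along(th),
                     theta_rel = runif(length(th), 0, 2 * pi))
  m2 <- merge_feature_angles(list(tr1, tr1, junk))
  expect_equal(attr(m2, "excluded"), 3L)
})

test_that("angular velocity is exact on linear and constant traces", {
  t <- (0:99) / 30
  expect_equal(angular_velocity(t, t), rep(1, 100))
  expect_equal(angular_velocity(rep(2, 100), t), rep(0, 100))
  expect_error(angular_velocity(t, t, smoothing_window = 999), "longer")
})

test_that("traction metric separates rolling, detachment and stalls", {
  prof <- adhesion_profile(NULL, 0.25)
  dyn <- simulate_rolling_dynamics(prof, cell_geometry(14), n_cycles = 4,
                                   detachment_intervals = list(c(2, 4)))
  trac <- traction_classification(dyn$theta, dyn$x, 7)
  roll <- !dyn$detached
  core_roll <- roll & c(roll[-1], TRUE) & c(TRUE, roll[-nrow(dyn)])
  expect_equal(mean(trac$metric[core_roll], na.rm = TRUE), 1, tolerance = 0.05)
  # detachment recall and precision
  lab_det <- trac$label == "detached"
  expect_gt(sum(lab_det & !roll) / sum(!roll), 0.9)
  expect_gt(sum(lab_det & !roll) / sum(lab_det), 0.9)
  # stalled cell -> ambiguous, not an error
  still <- traction_classification(rep(1, 20), rep(3, 20), 7)
  expect_true(all(still$label == "ambiguous"))
})

test_that("diameter from the theta-x slope is exact and guarded", {
  prof <- adhesion_profile(NULL, 0.25)
  dyn <- simulate_rolling_dynamics(prof, cell_geometry(14), n_cycles = 5)
  d <- circumference_from_slope(dyn$theta, dyn$x)
  expect_equal(as.numeric(d), 14, tolerance = 1e-6)
  expect_equal(attr(d, "slope"), 2 / 14, tolerance = 1e-6)
  dyn2 <- simulate_rolling_dynamics(prof, cell_geometry(14), n_cycles = 2)
  expect_error(circumference_from_slope(dyn2$theta, dyn2$x), "cycles")
})

test_that("reconstruction agrees with the joint grid-search oracle", {
  prof <- std_profile()
  dyn <- simulate_rolling_dynamics(prof, cell_geometry(14), n_cycles = 4)
  spots_R <- c(4.7, 3.9)
  spots_phi <- c(0.4, 2.1)
  trajs <- lapply(1:2, function(s)
    data.frame(frame = seq_len(nrow(dyn)),
               x_cm = spots_R[s] * cos(dyn$theta + spots_phi[s]), y_cm = 0))
  angs <- lapply(1:2, function(s)
    reconstruct_angle(trajs[[s]], spots_R[s]))
  merged <- merge_feature_angles(angs)
  cum <- accumulate_angle(merged$theta_rel)
  idx <- round(seq(2, nrow(dyn) - 1, length.out = 40))
  oracle <- vapply(idx, function(i)
    angle_oracle(c(trajs[[1]]$x_cm[i], trajs[[2]]$x_cm[i]), spots_R,
                 spots_phi),
    numeric(1))
  # compare mod 2pi after removing the merged trace's constant phase
  rec <- cum[idx]
  off <- atan2(mean(sin(rec - oracle)), mean(cos(rec - oracle)))
  d <- (rec - oracle - off) %% (2 * pi)
  d <- pmin(d, 2 * pi - d)
  expect_lt(max(d), 0.02)
})
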