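test_that("dwell time is 1/omega with a floor on stalls", {
  n <- 60
  th <- seq(0, 4 * pi, length.out = n)
  om <- rep(2 * pi / 10, n)
  dw <- dwell_time(th, om)
  expect_equal(dw$tau, rep(10 / (2 * pi), n), tolerance = 1e-12)
  om2 <- om; om2[5] <- 0
  dw2 <- dwell_time(th, om2)
  expect_equal(attr(dw2, "n_excluded"), 1L)
  expect_equal(nrow(dw2), n - 1L)
  expect_error(dwell_time(th, rep(0, n)), "omega")
})

test_that("a strong patch appears in the dwell at the right contrast", {
  prof <- adhesion_profile(data.frame(center = pi, width = pi / 2,
                                      multiplier = 9), 0.1)
  dyn <- simulate_rolling_dynamics(prof, cell_geometry(14), n_cycles = 5)
  dw <- dwell_time(dyn$theta, dyn$omega)
  inside <- profile_dwell(prof, dw$theta) > 0.5
  expect_equal(mean(dw$tau[inside]) / mean(dw$tau[!inside]), 10,
               tolerance = 0.15)
})

test_that("stacking identical cycles gives zero SD; patches land in the right bins", {
  th <- seq(0, 10 * pi, by = 2 * pi / 200)
  prof <- std_profile()
  tau <- profile_dwell(prof, th)
  dm <- stack_dwell_periods(th, tau, n_bins = 100)
  expect_gte(dm$n_cycles, 4L)
  expect_lt(max(dm$sd, na.rm = TRUE), 1e-10)
  # bin means reproduce the patch positions within one bin
  truth <- profile_dwell(prof, dm$bin_centers)
  expect_gt(cor(dm$mean, truth), 0.98)
  peak_bin <- which.max(dm$mean)
  true_peak_bins <- which(truth == max(truth))
  expect_lte(min(abs(peak_bin - true_peak_bins)), 1)
  expect_error(stack_dwell_periods(th[th < 2 * pi], tau[th < 2 * pi]),
               "2 complete")
})

test_that("stacked means of a flat noisy profile sit within 3 SE of baseline", {
  set.seed(21)
  ok <- vapply(1:50, function(s) {
    th <- seq(0, 16 * pi, by = 2 * pi / 100)
    tau <- 0.5 + rnorm(length(th), 0, 0.05)
    dm <- stack_dwell_periods(th, tau, n_bins = 50)
    se <- dm$sd / sqrt(dm$n_cycles)
    mean(abs(dm$mean - 0.5) <= 3 * pmax(se, 1e-12))
  }, numeric(1))
  expect_gte(mean(ok), 0.95)
})

test_that("stacked mean is invariant to cycle permutation", {
  set.seed(3)
  th <- seq(0, 8 * pi, by = 2 * pi / 100)
  tau <- profile_dwell(std_profile(), th) + rnorm(length(th), 0, 0.02)
  dm <- stack_dwell_periods(th, tau)
  perm <- dm$tau_cycles[sample(nrow(dm$tau_cycles)), ]
  expect_equal(colMeans(perm, na.rm = TRUE), dm$mean)
})

test_that("cosine dwell gives near-unit autocorrelation peaks at 2n*pi", {
  th <- seq(0, 16 * pi, by = 2 * pi / 100)
  tau <- 1 + cos(th)
  res <- dwell_autocorrelation(tau[-length(tau)], max_lag = 6.5 * pi)
  expect_equal(res$acf[1], 1)
  expect_true(all(1:3 %in% res$peaks$order))
  expect_true(all(res$peaks$value[res$peaks$order <= 3] >= 0.9))
  expect_equal(res$period, 2 * pi, tolerance = 0.05)
  # acf approximately follows cos(lag)
  expect_equal(res$acf[which.min(abs(res$lag - pi))], -1, tolerance = 0.1)
})

test_that("white-noise dwell shows no 2*pi peak above the 3/sqrt(N) threshold", {
  set.seed(8)
  hits <- vapply(1:100, function(s) {
    tau <- rnorm(500)
    res <- dwell_autocorrelation(tau, delta = 2 * pi / 100,
                                 max_lag = 2.5 * pi,
                                 min_height = 3 / sqrt(500))
    !is.null(res$peaks) && 1 %in% res$peaks$order
  }, logical(1))
  expect_lt(mean(hits), 0.1)
})

test_that("non-uniform grids are rejected by the autocorrelation", {
  th <- cumsum(runif(400, 0.01, 0.1))
  expect_error(dwell_autocorrelation(rep(1, 400), theta = th), "resample")
})

test_that("patch size fraction recovers top-hat widths across the printed range", {
  for (w in c(pi / 6, pi / 2, 5 * pi / 6)) {
    prof <- adhesion_profile(data.frame(center = pi, width = w,
                                        multiplier = 30), 0.1)
    th <- seq(0, 12 * pi, by = 2 * pi / 400)
    tau <- profile_dwell(prof, th)
    res <- dwell_autocorrelation(tau[-length(tau)], delta = 2 * pi / 400)
    frac <- patch_size_fraction(res)
    # the top-hat inversion is ill-conditioned for the widest patches
    # (d fraction / d FWHM diverges as FWHM/P -> 1/4)
    tol <- if (w > pi / 2) 0.02 else 0.01
    expect_lt(abs(as.numeric(frac) - w / (2 * pi)), tol)
  }
  # flat + noise: fraction collapses to the grid scale
  set.seed(4)
  tau <- rnorm(1200)
  res <- dwell_autocorrelation(tau, delta = 2 * pi / 100)
  expect_lt(as.numeric(patch_size_fraction(res)), 0.02)
})

test_that("patch size fraction flags an autocorrelation that never halves", {
  th <- seq(0, 12 * pi, by = 2 * pi / 100)
  tau <- 1 + 0.1 * cos(th / 6)   # period longer than the window
  res <- dwell_autocorrelation(tau[-length(tau)], max_lag = 2 * pi)
  frac <- patch_size_fraction(res)
  expect_equal(as.numeric(frac), 0.5)
  expect_true(attr(frac, "flagged"))
})

test_that("polar map renders and the dwell CSV round-trips", {
  th <- seq(0, 8 * pi, by = 2 * pi / 100)
  tau <- profile_dwell(std_profile(), th)
  dm <- stack_dwell_periods(th, tau)
  p <- polar_map(dm)
  expect_s3_class(p, "ggplot")
  f <- tempfile(fileext = ".csv")
  write_dwell_csv(dm, f)
  back <- read.csv(f)
  expect_equal(back$tau_mean, dm$mean, tolerance = 1e-12)
  expect_equal(back$angle_rad, dm$bin_centers, tolerance = 1e-12)
  unlink(f)
})

test_that("a single cell without detachment keeps its positional periodicity", {
  prof <- std_profile()
  geom <- cell_geometry(14)
  dyn <- simulate_rolling_dynamics(prof, geom, n_cycles = 6)
  tr <- list(list(x = dyn$x, tau = 7 / pmax(dyn$v, 0.5)))
  pos <- positional_dwell_autocorrelation(tr, mean_diameter = 14)
  pk <- pos$average$peaks
  expect_false(is.null(pk))
  expect_true(1 %in% pk$order)
  expect_equal(pk$lag[pk$order == 1], pi * 14, tolerance = 0.05 * pi * 14)
  expect_error(positional_dwell_autocorrelation(list(), 14), "empty")
})
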