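pxf <- 0.16

test_that("illumination correction follows the flat-field formula exactly", {
  I0 <- matrix(200, 8, 8)
  expect_equal(correct_illumination(I0, I0), matrix(0, 8, 8))
  expect_equal(correct_illumination(I0, 0, 1), I0)
  expect_equal(correct_illumination(matrix(200, 1, 1), 100, 0.5)[1, 1], 200)
  expect_error(correct_illumination(I0, matrix(0, 4, 4)), "dimensions")
  # pixels under the illumination floor are masked and counted
  illum <- matrix(1, 8, 8); illum[1, 1] <- 1e-9
  out <- correct_illumination(I0, 0, illum, eps = 1e-3)
  expect_equal(attr(out, "n_masked"), 1L)
  expect_equal(out[1, 1], 0)
})

test_that("flat tiles give a unit illumination profile; one tile warns", {
  tiles <- replicate(5, matrix(7, 16, 16), simplify = FALSE)
  prof <- estimate_illumination(tiles, dark_frame = 0)
  expect_equal(prof, matrix(1, 16, 16))
  expect_warning(estimate_illumination(tiles[1], 0), "single image")
  expect_error(estimate_illumination(lapply(tiles, function(t) t * 0), 0),
               "non-positive")
})

test_that("the illumination field is recovered from many sparse-spot tiles", {
  set.seed(14)
  vig <- make_vignette(c(64, 64), 0.5)
  tiles <- lapply(1:250, function(k) {
    (random_spot_tile(c(64, 64), rpois(1, 80), sigma_px = 1.5) + 20) * vig
  })
  est <- estimate_illumination(tiles, dark_frame = 0, smooth_sigma_px = 4)
  expect_lt(sqrt(mean((est - vig)^2)), 0.02)
  # correcting with the estimate instead of the true field leaves a
  # multiplicative flat-field residual est/vig with CV < 2%
  resid_field <- est / vig
  expect_lt(stats::sd(resid_field) / mean(resid_field), 0.02)
})

test_that("stitching recovers exact integer offsets and joins without blending", {
  prof <- std_profile()
  geom <- cell_geometry(14)
  fp <- footprint_sim_params(noise_sd = 0.5)
  sim <- simulate_footprint_tiles(prof, geom, fp, track_length_cycles = 3,
                                  seed = 6)
  st <- stitch_tiles(sim$tiles, nominal_overlap_px = fp$tile_overlap)
  expect_identical(st$offsets$x_px, as.integer(sim$truth$tile_offsets_px))
  expect_true(all(st$offsets$y_px == 0L))
  expect_false(any(st$offsets$fallback))
  # pixels outside overlaps come through unchanged (no averaging)
  expect_equal(st$mosaic[, 1:10], sim$tiles[[1]][, 1:10])
})

test_that("featureless overlaps fall back to the nominal offset with a flag", {
  tiles <- list(matrix(5, 64, 64), matrix(5, 64, 64))
  st <- stitch_tiles(tiles, nominal_overlap_px = 16)
  expect_true(st$offsets$fallback[2])
  expect_equal(st$offsets$x_px[2], 48L)
  single <- stitch_tiles(list(matrix(1:100, 10, 10)), 8)
  expect_equal(single$mosaic, matrix(1:100, 10, 10))
  expect_error(stitch_tiles(tiles, 4), "at least 8")
})

test_that("stitching introduces no artificial periodicity at the tile width", {
  prof <- adhesion_profile(NULL, 0.3)   # flat bead-like track
  geom <- cell_geometry(14)
  fp <- footprint_sim_params(noise_sd = 0.5,
                             illum_field = make_vignette(c(128, 128), 0.3))
  sim <- simulate_footprint_tiles(prof, geom, fp, track_length_cycles = 4,
                                  seed = 15)
  illum <- estimate_illumination(sim$tiles, fp$background_level,
                                 smooth_sigma_px = 16)
  corr <- lapply(sim$tiles, correct_illumination, Ibg = fp$background_level,
                 illum = illum, eps = 0.25)
  st <- stitch_tiles(corr, fp$tile_overlap)
  prof1 <- colSums(st$mosaic)
  rho <- acf_biased(prof1, 500L)
  stride <- 128L - fp$tile_overlap
  expect_lt(max(rho[(stride - 2):(stride + 2) + 1L]), 3 / sqrt(length(prof1)) + 0.1)
})

test_that("cross-correlation finds an embedded unit with score 1 at the true offset", {
  set.seed(16)
  img <- matrix(runif(60 * 400), 60, 400)
  unit <- img[, 101:180]
  xc <- track_cross_correlation(img, unit, pixel_size = pxf, threshold = 0.9)
  expect_equal(max(xc$profile), 1, tolerance = 1e-8)
  expect_equal(which.max(xc$profile), 101L)
})

test_that("track cross-correlation recovers the rolling period within 2 px", {
  prof <- std_profile()
  geom <- cell_geometry(14)
  sim <- simulate_footprint_tiles(prof, geom, footprint_sim_params(noise_sd = 0.5),
                                  track_length_cycles = 5, seed = 3)
  img <- sim$full_image
  per_px <- round(pi * 14 / pxf)
  unit <- img[, 300:(300 + per_px - 1)]
  xc <- track_cross_correlation(img, unit, pixel_size = pxf)
  expect_lt(abs(xc$period_px - pi * 14 / pxf), 2)
  # averaging the periods reduces independent noise roughly as sqrt(n)
  avg <- average_period_unit(img, xc$period_px, xc$peak_x_px)
  expect_gte(avg$n_used, 2L)
  expect_error(average_period_unit(img, xc$period_px, xc$peak_x_px[1]),
               "at least 2")
})

test_that("flat-profile (bead-analogue) tracks show no repeated correlation peaks", {
  prof <- adhesion_profile(NULL, 0.3)
  geom <- cell_geometry(14)
  sim <- simulate_footprint_tiles(prof, geom, footprint_sim_params(noise_sd = 0.5),
                                  track_length_cycles = 5, seed = 18)
  img <- sim$full_image
  fac <- footprint_autocorrelation(img, 14, pxf, min_height = 0.15)
  expect_true(is.null(fac$peaks) || !(1 %in% fac$peaks$order))
})

test_that("averaging identical repeats returns one repeat; noise shrinks ~sqrt(n)", {
  set.seed(17)
  unit <- random_spot_tile(c(40, 50), 30, 1.5)
  clean <- do.call(cbind, replicate(8, unit, simplify = FALSE))
  peaks <- 50 * (0:7) + 25.5   # true window centers for width-50 units
  avg <- average_period_unit(clean, 50, peaks)
  expect_equal(avg$unit_mean, unit, tolerance = 1e-12)
  noisy <- clean + matrix(rnorm(length(clean), 0, 2), nrow(clean))
  avg_n <- average_period_unit(noisy, 50, peaks)
  resid <- avg_n$unit_mean - unit
  expect_equal(stats::sd(resid), 2 / sqrt(8), tolerance = 0.2)
})

test_that("footprint autocorrelation peaks at one circumference (and harmonics)", {
  prof <- adhesion_profile(data.frame(center = pi, width = pi / 2,
                                      multiplier = 9), 0.3)
  geom <- cell_geometry(14)
  sim <- simulate_footprint_tiles(prof, geom, footprint_sim_params(noise_sd = 0.5),
                                  track_length_cycles = 5, seed = 19)
  fac <- footprint_autocorrelation(sim$full_image, 14, pxf)
  expect_true(1 %in% fac$peaks$order)
  pk1 <- fac$peaks$lag[fac$peaks$order == 1]
  expect_equal(pk1, 1, tolerance = 0.05)
  expect_equal(fac$period_um, pi * 14, tolerance = 0.32)  # 2 px at 0.16 um/px
  # a patch every half turn doubles the peak comb
  prof2 <- adhesion_profile(data.frame(center = c(0, pi),
                                       width = c(pi / 3, pi / 3),
                                       multiplier = c(9, 9)), 0.3)
  sim2 <- simulate_footprint_tiles(prof2, geom,
                                   footprint_sim_params(noise_sd = 0.5),
                                   track_length_cycles = 5, seed = 20)
  band <- colSums(sim2$full_image)
  rho <- acf_biased(band, round(1.2 * pi * 14 / pxf))
  half <- round(pi * 14 / 2 / pxf)
  expect_gt(rho[half + 1], 0.3)
  expect_error(footprint_autocorrelation(sim$full_image[1:2, ], 14, pxf),
               "3 px")
})

test_that("contact width is recovered within 2 px and is scale invariant", {
  prof <- std_profile()
  geom <- cell_geometry(14)
  sim <- simulate_footprint_tiles(prof, geom,
                                  footprint_sim_params(noise_sd = 0.5),
                                  track_length_cycles = 4, seed = 21)
  w <- contact_width(sim$full_image, pxf)
  expect_equal(as.numeric(w), 5.7, tolerance = 2 * pxf)
  w10 <- contact_width(sim$full_image * 10, pxf)
  expect_equal(as.numeric(w10), as.numeric(w))
  expect_error(contact_width(matrix(0, 100, 100), pxf), "background")
})

test_that("contact geometry reproduces the closed-form area and fraction", {
  g <- contact_geometry(5.7, 14.1)
  expect_equal(signif(g$area_um2, 2), 26)
  expect_equal(round(g$fraction_pct), 4)
  # width = d/2 gives exactly 6.25 %
  g2 <- contact_geometry(7, 14)
  expect_equal(g2$fraction_pct, 6.25)
  expect_error(contact_geometry(15, 14), "smaller than the diameter")
})

test_that("correct-then-stitch equals stitch-then-correct away from seams", {
  prof <- std_profile()
  geom <- cell_geometry(14)
  vig <- make_vignette(c(128, 128), 0.3)
  fp <- footprint_sim_params(illum_field = vig, background_level = 0)
  sim <- simulate_footprint_tiles(prof, geom, fp, track_length_cycles = 3,
                                  seed = 22)
  corr_first <- stitch_tiles(lapply(sim$tiles, correct_illumination,
                                    Ibg = 0, illum = vig),
                             fp$tile_overlap)
  st <- stitch_tiles(sim$tiles, fp$tile_overlap)
  # correct the mosaic column-by-column using the tile that owns each
  # column (later tiles own the overlap, matching the join rule)
  stitched_then <- st$mosaic
  tw <- 128L
  n <- nrow(st$offsets)
  for (k in seq_len(n)) {
    last_col <- if (k < n) st$offsets$x_px[k + 1L] else st$offsets$x_px[k] + tw
    cols <- (st$offsets$x_px[k] + 1L):last_col
    local <- cols - st$offsets$x_px[k]
    stitched_then[, cols] <- stitched_then[, cols] / vig[, local]
  }
  expect_equal(corr_first$mosaic, stitched_then, tolerance = 1e-9)
})

test_that("track ROI isolation finds the band and its rows cover the truth", {
  prof <- std_profile()
  geom <- cell_geometry(14)
  sim <- simulate_footprint_tiles(prof, geom,
                                  footprint_sim_params(noise_sd = 0.5),
                                  track_length_cycles = 3, seed = 23)
  rois <- isolate_track_roi(sim$full_image, pxf)
  expect_equal(length(rois), 1L)
  rows_um <- range(rois[[1]]$rows) * pxf
  expect_lt(rows_um[1], sim$truth$band_center_um - 5.7 / 2 + 1)
  expect_gt(rows_um[2], sim$truth$band_center_um + 5.7 / 2 - 1)
})

test_that("periodicity prevalence is the printed percentage", {
  expect_equal(round(prevalence_pct(51, 63)), 81)
  expect_equal(prevalence_pct(0, 10), 0)
  expect_error(prevalence_pct(5, 0), "n_total")
  expect_error(prevalence_pct(11, 10), "n_periodic")
})
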