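px <- 0.53

# one rendered frame with the cell at a known position
one_cell_frame <- function(seed = 1, spots = NULL) {
  prof <- adhesion_profile(NULL, 0.2)
  geom <- cell_geometry(14, spots = spots)
  mv <- simulate_rolling_movie(prof, geom, imaging_params(), n_cycles = 1,
                               seed = seed)
  list(frame = mv$movie[, , 1],
       truth = c(mv$truth$frames$x_world[1], mv$truth$frames$y_world[1]))
}

test_that("segmentation finds the cell centroid within the tracking precision", {
  oc <- one_cell_frame()
  det <- segment_cells(oc$frame, px)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x_um - oc$truth[1]), 0.5)
  expect_lt(abs(det$y_um - oc$truth[2]), 0.5)
})

test_that("uniform frames give zero regions; two cells give two ordered regions", {
  expect_equal(nrow(segment_cells(matrix(5, 40, 60), px)), 0L)
  oc <- one_cell_frame()
  two <- cbind(oc$frame, matrix(min(oc$frame), nrow(oc$frame), 10), oc$frame)
  det <- segment_cells(two, px)
  expect_equal(nrow(det), 2L)
  expect_true(det$x_um[1] < det$x_um[2])
})

test_that("linking produces one full-length track and splits at long gaps", {
  det <- data.frame(frame = 1:30, x_um = (1:30) * 0.4, y_um = 5,
                    area_px = 100)
  tr <- link_cell_tracks(det, max_jump_um = 2, frame_interval = 1 / 30)
  expect_length(tr, 1L)
  expect_equal(nrow(tr[[1]]), 30L)
  expect_equal(tr[[1]]$t, (0:29) / 30)
  # disappearance longer than the gap tolerance splits the track
  det2 <- det[det$frame <= 10 | det$frame >= 16, ]
  tr2 <- link_cell_tracks(det2, max_jump_um = 2, gap_frames = 2L)
  expect_length(tr2, 2L)
  # each detection used at most once: total linked rows = detections
  expect_equal(sum(vapply(tr2, nrow, 1L)), nrow(det2))
})

test_that("linked positions on a synthetic movie match truth with RMS < 0.5 um", {
  ch <- run_chain("flat2", adhesion_profile(NULL, 0.2),
                  cell_geometry(14, spots = std_spots(2)), n_cycles = 4.5)
  tru <- ch$mv$truth$frames
  err <- sqrt((ch$track$x_um - tru$x_world[ch$track$frame])^2 +
                (ch$track$y_um - tru$y_world[ch$track$frame])^2)
  expect_lt(sqrt(mean(err^2)), 0.5)
  expect_gte(nrow(ch$track), 0.98 * nrow(tru))
})

test_that("velocity is exact for uniform motion, v = r*omega for rolling, 0 when stalled", {
  tr <- data.frame(frame = 1:20, t = (0:19) * 0.1, x_um = (0:19) * 0.5,
                   y_um = 0)
  expect_equal(cell_velocity(tr), rep(5, 20))
  # pure rolling at omega = 1 rad/s, r = 7 um
  prof <- adhesion_profile(NULL, 1)   # tau = 1 s/rad -> omega = 1
  dyn <- simulate_rolling_dynamics(prof, cell_geometry(14), n_cycles = 1)
  v <- cell_velocity(data.frame(t = dyn$t, x_um = dyn$x))
  expect_equal(mean(v), 7, tolerance = 0.01)
  still <- data.frame(t = (0:9) * 0.1, x_um = rep(2, 10))
  expect_equal(cell_velocity(still), rep(0, 10))
  expect_error(cell_velocity(tr, smoothing_window = 99), "longer")
})

test_that("cell-centered crops align with the cell and flag edge padding", {
  ch <- run_chain("flat2", adhesion_profile(NULL, 0.2),
                  cell_geometry(14, spots = std_spots(2)), n_cycles = 4.5)
  st <- ch$stack
  # residuals are sub-pixel by construction
  expect_true(all(abs(st$residual_um$dx_um) <= px / 2 + 1e-9))
  # frame-change identity: features detected in the crop, expressed in the
  # cell frame, match the true world trajectory minus the centroid
  tru <- ch$mv$truth
  for (f in ch$track$frame[c(10, 50, 100)]) {
    x_cm_truth <- tru$spots$R[1] * cos(tru$frames$theta[f] + tru$spots$phi[1])
    got <- ch$feats$x_cm[ch$feats$frame == f]
    expect_lt(min(abs(got - x_cm_truth)), 0.2)
  }
  # cropping at the movie edge pads and flags
  small <- ch$mv$movie[, 1:30, ]
  tr_edge <- ch$track[1:3, ]
  st2 <- crop_cell_frame(small, tr_edge, 9, px)
  expect_true(any(st2$padded))
})

test_that("tracks outside the movie are rejected and CSV export round-trips", {
  mov <- array(0, dim = c(20, 20, 2))
  bad <- data.frame(frame = 1:2, x_um = c(5, 500), y_um = 5, t = 0:1)
  expect_error(crop_cell_frame(mov, bad, 3, px), "outside")
  tr <- data.frame(frame = 1:5, t = (0:4) / 30, x_um = 1:5, y_um = 0,
                   area_px = 60)
  f <- tempfile(fileext = ".csv")
  write_track_csv(tr, f)
  back <- read.csv(f)
  expect_equal(back$x_um, tr$x_um)
  unlink(f)
})
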