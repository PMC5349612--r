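# End-to-end pipelines: configuration, logging, dataset round-tripping.

# Polynomial rolling hash of a canonical serialization of the config (hex
# string); stamped into every numeric output so results are traceable to
# the settings that produced them.
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

load_config <- function(config, required) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys) > 0L) {
    stop("config is missing required key(s): ",
         paste(missing_keys, collapse = ", "))
  }
  config
}

prepare_output_dir <- function(dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    stop("output directory ", dir, " is not empty; use force = TRUE to ",
         "overwrite")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  invisible(dir)
}

# CSV with a hash comment line; read back with read.csv(comment.char = "#")
write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the rotation-tracking and adhesion-mapping pipeline
#'
#' Chains segmentation, track linking, cell-centered cropping, spot
#' detection and linking, angle reconstruction and merging, traction
#' classification, circumference estimation, dwell-time stacking and
#' autocorrelation, and writes per-cell CSV outputs, figures and a QC
#' table. Cells failing the minimum-cycles criterion appear in the QC table
#' with the failure reason rather than being dropped silently.
#'
#' @param config A list or YAML path. Required keys: `movie` (multi-page
#'   TIFF path) or `movie_array` (in-memory 3D array), `pixel_size` (um/px),
#'   `frame_interval` (s), `output_dir`. Optional keys with defaults:
#'   `min_area_px` (50), `max_jump_um` (8), `box_half_width_um` (9),
#'   `detector` ("mser"), `gate_um` (2.5), `smoothing_window` (5),
#'   `n_bins` (100), `min_cycles` (4), `seed` (1), `force` (FALSE).
#' @return Invisibly, a list with `tracks`, `results` (per-cell analysis),
#'   `qc` (data.frame), `hash`.
#' @export
run_rotation_pipeline <- function(config) {
  config <- load_config(config, c("pixel_size", "frame_interval",
                                  "output_dir"))
  if (is.null(config$movie) && is.null(config$movie_array)) {
    stop("config is missing required key(s): movie")
  }
  px <- config$pixel_size
  dt <- config$frame_interval
  hash <- config_hash(config[setdiff(names(config),
                                     c("movie_array", "output_dir", "force"))])
  out_dir <- prepare_output_dir(config$output_dir, isTRUE(config$force))
  ok <- FALSE
  on.exit(if (!ok) unlink(list.files(out_dir, full.names = TRUE)))

  movie <- if (!is.null(config$movie_array)) config$movie_array else {
    if (!file.exists(config$movie)) {
      stop("movie not readable: ", config$movie)
    }
    read_movie_tiff(config$movie)
  }
  p <- function(key, default) config[[key]] %||% default
  message("[rollmap] segmenting ", dim(movie)[3], " frames (hash ", hash, ")")
  det <- segment_movie(movie, px, min_area_px = p("min_area_px", 50))
  tracks <- link_cell_tracks(det, max_jump_um = p("max_jump_um", 8),
                             frame_interval = dt,
                             min_length = p("min_track_frames", 20))
  qc <- NULL
  results <- list()
  for (ci in seq_along(tracks)) {
    tr <- tracks[[ci]]
    res <- tryCatch({
      stack <- crop_cell_frame(movie, tr, p("box_half_width_um", 9), px)
      feats <- detect_spot_features(stack, method = p("detector", "mser"))
      trajs <- link_spot_trajectory(feats, gate_um = p("gate_um", 2.5))
      if (length(trajs) == 0L) stop("no spot trajectories")
      angs <- lapply(trajs, function(tj) {
        R <- estimate_radial_distance(tj, estimator = "percentile")
        reconstruct_angle(tj, R)
      })
      merged <- merge_feature_angles(angs)
      cum <- accumulate_angle(merged$theta_rel)
      tt <- (merged$frame - 1L) * dt
      om <- angular_velocity(cum, tt, p("smoothing_window", 5))
      xs <- tr$x_um[match(merged$frame, tr$frame)]
      r0 <- px * sqrt(stats::median(tr$area_px) / pi)  # from segmented area
      trac <- traction_classification(cum, xs, r0)
      d_est <- circumference_from_slope(cum, xs, trac$label,
                                        min_cycles = p("min_cycles", 4))
      dw <- dwell_time(cum, om, trac$label)
      dmap <- stack_dwell_periods(dw$theta, dw$tau, p("n_bins", 100))
      rs <- resample_dwell(dw$theta, dw$tau, 2 * pi / p("n_bins", 100))
      acf_res <- dwell_autocorrelation(rs$tau, delta = 2 * pi / p("n_bins", 100))
      list(track = tr, angle = data.frame(frame = merged$frame, t = tt,
                                          theta_rel = merged$theta_rel,
                                          theta_cum = cum, omega = om,
                                          label = trac$label,
                                          slope_metric = trac$metric),
           diameter = d_est, dwell_map = dmap, acf = acf_res)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      qc <- rbind(qc, data.frame(cell = ci, n_frames = nrow(tr),
                                 status = "failed",
                                 reason = conditionMessage(res)))
      next
    }
    qc <- rbind(qc, data.frame(cell = ci, n_frames = nrow(tr),
                               status = "ok", reason = ""))
    results[[length(results) + 1L]] <- res
    tag <- sprintf("cell%02d", ci)
    write_stamped_csv(data.frame(frame = tr$frame, t = tr$t, x_um = tr$x_um,
                                 y_um = tr$y_um,
                                 v_um_s = cell_velocity(tr)),
                      file.path(out_dir, paste0(tag, "_track.csv")), hash)
    write_stamped_csv(res$angle,
                      file.path(out_dir, paste0(tag, "_angle.csv")), hash)
    write_stamped_csv(data.frame(angle_rad = res$dwell_map$bin_centers,
                                 tau_mean = res$dwell_map$mean,
                                 tau_sd = res$dwell_map$sd),
                      file.path(out_dir, paste0(tag, "_dwell.csv")), hash)
    write_stamped_csv(data.frame(lag_rad = res$acf$lag, acf = res$acf$acf),
                      file.path(out_dir, paste0(tag, "_acf.csv")), hash)
    polar_map(res$dwell_map, file.path(out_dir, paste0(tag, "_polar.png")))
  }
  if (is.null(qc)) {
    qc <- data.frame(cell = integer(0), n_frames = integer(0),
                     status = character(0), reason = character(0))
  }
  write_stamped_csv(qc, file.path(out_dir, "qc.csv"), hash)
  yaml::write_yaml(c(config[setdiff(names(config), "movie_array")],
                     list(config_hash = hash)),
                   file.path(out_dir, "config_used.yaml"))
  ok <- TRUE
  invisible(list(tracks = tracks, results = results, qc = qc, hash = hash))
}

#' Run the adhesion-footprint image pipeline
#'
#' Chains illumination estimation, flat-field correction, tile stitching,
#' track isolation, cross-correlation period detection, single-period
#' averaging, 1D autocorrelation, and contact geometry; writes the mosaic
#' and illumination profile (for audit) plus per-track CSV outputs.
#'
#' @param config A list or YAML path. Required keys: `tiles` (list of
#'   matrices, 3D array, or directory of single-page TIFFs), `pixel_size`,
#'   `nominal_overlap_px`, `output_dir`. Optional: `dark_frame` (matrix or
#'   TIFF path; if absent, correction uses zero background and sets a
#'   warning flag), `diameter` (um; estimated from the footprint period if
#'   absent), `force` (FALSE).
#' @return Invisibly, a list with `mosaic`, `offsets`, `tracks`
#'   (per-track geometry/periodicity data.frame), `hash`, `flags`.
#' @export
run_footprint_pipeline <- function(config) {
  config <- load_config(config, c("tiles", "pixel_size",
                                  "nominal_overlap_px", "output_dir"))
  px <- config$pixel_size
  hash <- config_hash(config[setdiff(names(config),
                                     c("tiles", "dark_frame", "output_dir",
                                       "force"))])
  out_dir <- prepare_output_dir(config$output_dir, isTRUE(config$force))
  ok <- FALSE
  on.exit(if (!ok) unlink(list.files(out_dir, full.names = TRUE)))

  tiles <- config$tiles
  if (is.character(tiles)) {
    paths <- sort(list.files(tiles, pattern = "\\.tiff?$", full.names = TRUE))
    paths <- paths[!grepl("dark", basename(paths))]
    if (length(paths) == 0L) stop("no TIFF tiles found in ", tiles)
    tiles <- lapply(paths, function(pth) {
      m <- tiff::readTIFF(pth)
      if (length(dim(m)) == 3L) m[, , 1] else m
    })
  }
  tiles <- as_tile_list(tiles)
  flags <- character(0)
  dark <- config$dark_frame
  if (is.character(dark)) {
    dark <- tiff::readTIFF(dark)
    if (length(dim(dark)) == 3L) dark <- dark[, , 1]
  }
  if (is.null(dark)) {
    dark <- 0
    flags <- c(flags, "no_dark_frame")
    warning("no dark frame provided; correction uses zero background")
  }
  message("[rollmap] correcting and stitching ", length(tiles),
          " tiles (hash ", hash, ")")
  p <- function(key, default) config[[key]] %||% default
  # with few tiles the mean image is dominated by the sparse spots; heavy
  # smoothing and a floor keep the flat-field estimate usable
  illum <- estimate_illumination(tiles, dark,
                                 smooth_sigma_px = p("illum_smooth_px", 16))
  floor_i <- p("illum_floor", 0.25)
  corrected <- lapply(tiles, correct_illumination, Ibg = dark, illum = illum,
                      eps = floor_i)
  st <- stitch_tiles(corrected, config$nominal_overlap_px)
  mosaic <- st$mosaic

  rois <- isolate_track_roi(mosaic, px)
  if (length(rois) == 0L) {
    rois <- list(list(rows = seq_len(nrow(mosaic)),
                      cols = seq_len(ncol(mosaic))))
    flags <- c(flags, "no_track_roi_fallback_full_mosaic")
  }
  track_rows <- NULL
  for (ti in seq_along(rois)) {
    roi <- rois[[ti]]
    timg <- mosaic[roi$rows, roi$cols, drop = FALSE]
    row <- tryCatch({
      prof <- colSums(timg)
      nlag <- floor(0.8 * (length(prof) - 1L))
      rho <- acf_biased(prof, nlag)
      min_lag <- as.integer(round(p("min_period_um", 15) / px))
      pk <- local_maxima(rho, min_value = 0.1)
      pk <- pk[pk > min_lag]
      if (length(pk) == 0L) stop("no periodicity detected")
      period_px0 <- pk[which.max(rho[pk])] - 1L
      # repeating unit: one period centered on the brightest stretch
      csm <- moving_average(prof, min(51L, length(prof)))
      c0 <- clamp(which.max(csm) - period_px0 %/% 2L, 1L,
                  ncol(timg) - period_px0 + 1L)
      unit <- timg[, c0:(c0 + period_px0 - 1L), drop = FALSE]
      xc <- track_cross_correlation(timg, unit, pixel_size = px)
      if (!is.finite(xc$period_px)) stop("fewer than 2 correlation peaks")
      d_est <- config$diameter %||% (xc$period_um / pi)
      fac <- footprint_autocorrelation(timg, d_est, px)
      w <- contact_width(timg, px)
      geom <- contact_geometry(as.numeric(w), d_est)
      avg <- average_period_unit(timg, xc$period_px, xc$peak_x_px)
      data.frame(track = ti, period_um = xc$period_um,
                 period_acf_um = fac$period_um, diameter_um = d_est,
                 width_um = as.numeric(w), area_um2 = geom$area_um2,
                 fraction_pct = geom$fraction_pct,
                 n_periods_averaged = avg$n_used, status = "ok",
                 reason = "")
    }, error = function(e)
      data.frame(track = ti, period_um = NA, period_acf_um = NA,
                 diameter_um = NA, width_um = NA, area_um2 = NA,
                 fraction_pct = NA, n_periods_averaged = NA,
                 status = "failed", reason = conditionMessage(e)))
    track_rows <- rbind(track_rows, row)
  }
  scale <- max(mosaic)
  tiff::writeTIFF(clamp(mosaic / scale, 0, 1),
                  file.path(out_dir, "mosaic.tif"), bits.per.sample = 16L)
  tiff::writeTIFF(clamp(illum, 0, 1), file.path(out_dir, "illumination.tif"),
                  bits.per.sample = 16L)
  write_stamped_csv(st$offsets, file.path(out_dir, "tile_offsets.csv"), hash)
  write_stamped_csv(track_rows, file.path(out_dir, "tracks.csv"), hash)
  yaml::write_yaml(c(config[setdiff(names(config),
                                    c("tiles", "dark_frame"))],
                     list(config_hash = hash, flags = flags)),
                   file.path(out_dir, "config_used.yaml"))
  ok <- TRUE
  invisible(list(mosaic = mosaic, offsets = st$offsets, tracks = track_rows,
                 hash = hash, flags = flags))
}
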