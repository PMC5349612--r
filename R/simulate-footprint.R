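# Synthetic fluorescent adhesion-footprint tiles with known ground truth.

#' Parameters of the synthetic footprint assay
#'
#' The simulated readout of a digital molecular force sensor: a rolling cell
#' ruptures surface-bound DNA tethers wherever adhesive load exceeds the
#' rupture threshold, leaving fluorescent spots in a band (the contact
#' track) along the flow axis. Defaults follow the typical assay scale:
#' 5.7 um contact band, ~250 nm optical resolution, 0.16 um/px (100x).
#'
#' @param track_band_width Width of the contact track band in um (> 0).
#' @param rupture_density_scale Rupture events per um^2 per rolling pass at
#'   dwell multiplier 1; local density scales with the dwell profile.
#' @param rupture_force_threshold Digital rupture threshold in pN (recorded
#'   as provenance; the simulator is purely above-threshold).
#' @param psf_sigma Rendered spot sigma in um (optical resolution).
#' @param pixel_size um per pixel.
#' @param background_level Constant camera background per tile.
#' @param noise_sd Additive Gaussian noise SD per tile (0 = noise-free).
#' @param illum_field Normalized illumination profile, a matrix of
#'   `tile_shape` with values in (0, 1\] and max exactly 1, applied to every
#'   tile (the field is fixed to the camera frame); `NULL` = flat.
#' @param tile_shape Integer `c(ny, nx)` tile size in px.
#' @param tile_overlap Overlap between adjacent tiles in px (< tile width).
#' @return Object of class `footprint_sim_params`.
#' @export
footprint_sim_params <- function(track_band_width = 5.7,
                                 rupture_density_scale = 8,
                                 rupture_force_threshold = 12,
                                 psf_sigma = 0.25,
                                 pixel_size = 0.16,
                                 background_level = 5,
                                 noise_sd = 0,
                                 illum_field = NULL,
                                 tile_shape = c(128L, 128L),
                                 tile_overlap = 24L) {
  if (track_band_width <= 0) stop("track_band_width must be > 0")
  if (rupture_density_scale <= 0) stop("rupture_density_scale must be > 0")
  tile_shape <- as.integer(tile_shape)
  stopifnot(length(tile_shape) == 2L, all(tile_shape > 0L))
  if (tile_overlap >= tile_shape[2]) {
    stop("tile_overlap must be smaller than the tile width")
  }
  if (!is.null(illum_field)) {
    illum_field <- as.matrix(illum_field)
    if (!all(dim(illum_field) == tile_shape)) {
      stop("illum_field must have dimensions tile_shape")
    }
    if (any(illum_field <= 0) || abs(max(illum_field) - 1) > 1e-12) {
      stop("illum_field values must lie in (0, 1] with max exactly 1")
    }
  }
  structure(list(track_band_width = track_band_width,
                 rupture_density_scale = rupture_density_scale,
                 rupture_force_threshold = rupture_force_threshold,
                 psf_sigma = psf_sigma, pixel_size = pixel_size,
                 background_level = background_level, noise_sd = noise_sd,
                 illum_field = illum_field, tile_shape = tile_shape,
                 tile_overlap = as.integer(tile_overlap)),
            class = "footprint_sim_params")
}

#' Gaussian vignette illumination profile
#'
#' @param shape `c(ny, nx)` in px.
#' @param strength Fractional fall-off at the image corner (0 = flat).
#' @return Matrix with max 1, values in (0, 1].
#' @export
make_vignette <- function(shape, strength = 0.4) {
  ny <- shape[1]; nx <- shape[2]
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  d2 <- outer((seq_len(ny) - cy)^2, rep(1, nx)) +
    outer(rep(1, ny), (seq_len(nx) - cx)^2)
  d2max <- max(d2)
  v <- 1 - strength * d2 / d2max
  v / max(v)
}

# stamp a unit-amplitude Gaussian at (x_um, y_um) into image (in place-ish)
stamp_events <- function(img, x_um, y_um, sigma_um, px, amplitude = 1) {
  ny <- nrow(img); nx <- ncol(img)
  s_px <- sigma_um / px
  half <- max(2L, as.integer(ceiling(4 * s_px)))
  for (e in seq_along(x_um)) {
    cx <- x_um[e] / px + 0.5   # pixel-center coordinates
    cy <- y_um[e] / px + 0.5
    j0 <- max(1L, as.integer(floor(cx - half)))
    j1 <- min(nx, as.integer(ceiling(cx + half)))
    i0 <- max(1L, as.integer(floor(cy - half)))
    i1 <- min(ny, as.integer(ceiling(cy + half)))
    if (j0 > j1 || i0 > i1) next
    gx <- exp(-((j0:j1) - cx)^2 / (2 * s_px^2))
    gy <- exp(-((i0:i1) - cy)^2 / (2 * s_px^2))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + amplitude * outer(gy, gx)
  }
  img
}

#' Simulate adhesion-footprint image tiles
#'
#' Rupture events are drawn from an inhomogeneous Poisson process whose
#' surface density follows the adhesion profile sampled along the track,
#' \eqn{\lambda(x, y) = \rho_0 \, \tau(x/r \bmod 2\pi)/\tau_0 \times B(y)},
#' with \eqn{B} a top-hat of the track band width: more dwell means more
#' adhesive load above the digital rupture threshold and hence more events
#' per unit track length, so the footprint is bright where adhesion is
#' strong and repeats with period \eqn{\pi d}. Events are rendered as
#' Gaussians at the optical resolution, the image is multiplied by the
#' illumination field, background (and optional noise) is added, and the
#' result is split into overlapping tiles whose true offsets are recorded.
#'
#' @param profile An [adhesion_profile()].
#' @param geometry A [cell_geometry()].
#' @param fp_params A [footprint_sim_params()].
#' @param track_length_cycles Number of rolling cycles in the track (>= 2;
#'   periodicity analysis needs repeats).
#' @param seed Integer seed.
#' @param margin_um Blank margin before and after the track.
#' @return List of class `footprint_sim`: `tiles` (list of matrices),
#'   `dark_frame`, `illum_field`, `full_image` (the unsplit mosaic before
#'   tiling), and `truth` (events, true tile offsets in px, period pi*d,
#'   band geometry, pixel size, seed).
#' @export
simulate_footprint_tiles <- function(profile, geometry, fp_params = footprint_sim_params(),
                                     track_length_cycles = 4, seed = 1L,
                                     margin_um = 5) {
  stopifnot(inherits(profile, "adhesion_profile"),
            inherits(geometry, "cell_geometry"),
            inherits(fp_params, "footprint_sim_params"))
  if (track_length_cycles < 2) {
    stop("track_length_cycles must be >= 2 (periodicity needs repeats)")
  }
  set.seed(seed)
  px <- fp_params$pixel_size
  r <- geometry$radius
  period <- pi * geometry$diameter
  ny <- fp_params$tile_shape[1]
  H_um <- ny * px
  band <- fp_params$track_band_width
  if (band > H_um) {
    stop("track band (", band, " um) is wider than the tile height (",
         signif(H_um, 4), " um)")
  }
  track_len <- track_length_cycles * period
  L_um <- track_len + 2 * margin_um

  # --- tiling layout (pad so tiles exactly cover the image) ---
  tw <- fp_params$tile_shape[2]; ov <- fp_params$tile_overlap
  stride <- tw - ov
  nx_min <- as.integer(ceiling(L_um / px))
  n_tiles <- max(1L, as.integer(ceiling((nx_min - tw) / stride)) + 1L)
  nx <- (n_tiles - 1L) * stride + tw
  offsets <- (seq_len(n_tiles) - 1L) * stride   # 0-based column offsets

  # --- inhomogeneous Poisson events ---
  grid_n <- 4096L
  xg <- seq(0, track_len, length.out = grid_n + 1L)[-1] - track_len / (2 * grid_n)
  lambda_x <- fp_params$rupture_density_scale *
    profile_dwell(profile, xg / r) / profile$baseline_dwell   # events / um^2
  total_rate <- sum(lambda_x) * (track_len / grid_n) * band
  if (!is.finite(total_rate) || total_rate <= 0) {
    stop("event rate is zero everywhere; nothing to simulate")
  }
  n_events <- stats::rpois(1L, total_rate)
  cdf <- cumsum(lambda_x); cdf <- cdf / cdf[length(cdf)]
  ux <- stats::runif(n_events)
  x_ev <- margin_um + stats::approx(c(0, cdf), c(0, xg + track_len / (2 * grid_n)),
                                    xout = ux, ties = "ordered")$y
  y_center <- H_um / 2
  y_ev <- y_center + stats::runif(n_events, -band / 2, band / 2)

  img <- matrix(0, ny, nx)
  img <- stamp_events(img, x_ev, y_ev, fp_params$psf_sigma, px)

  # --- illumination, background, tiling ---
  illum <- fp_params$illum_field
  tiles <- vector("list", n_tiles)
  for (k in seq_len(n_tiles)) {
    cols <- (offsets[k] + 1L):(offsets[k] + tw)
    tile <- img[, cols, drop = FALSE]
    if (!is.null(illum)) tile <- tile * illum
    tile <- tile + fp_params$background_level
    if (fp_params$noise_sd > 0) {
      tile <- tile + matrix(stats::rnorm(length(tile), sd = fp_params$noise_sd),
                            nrow(tile), ncol(tile))
    }
    tiles[[k]] <- tile
  }
  dark <- matrix(fp_params$background_level, ny, tw)
  if (fp_params$noise_sd > 0) {
    dark <- dark + matrix(stats::rnorm(length(dark), sd = fp_params$noise_sd),
                          ny, tw)
  }
  truth <- list(
    events = data.frame(x_um = x_ev, y_um = y_ev),
    tile_offsets_px = offsets,
    period_um = period,
    band_center_um = y_center,
    band_width_um = band,
    pixel_size = px,
    track_start_um = margin_um,
    track_length_um = track_len,
    seed = seed
  )
  structure(list(tiles = tiles, dark_frame = dark,
                 illum_field = illum, full_image = img + fp_params$background_level,
                 truth = truth, fp_params = fp_params),
            class = "footprint_sim")
}

#' Write footprint tiles as single-page TIFF files
#'
#' @param sim A `footprint_sim` result.
#' @param dir Output directory (created if missing).
#' @param scale Intensity mapped to white; defaults to the global maximum.
#' @return Character vector of written paths (tiles then dark frame).
#' @export
write_footprint_tiffs <- function(sim, dir, scale = NULL) {
  stopifnot(inherits(sim, "footprint_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scale <- scale %||% max(unlist(lapply(sim$tiles, max)))
  paths <- character(0)
  for (k in seq_along(sim$tiles)) {
    p <- file.path(dir, sprintf("tile_%03d.tif", k))
    tiff::writeTIFF(clamp(sim$tiles[[k]] / scale, 0, 1), p,
                    bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  pd <- file.path(dir, "dark.tif")
  tiff::writeTIFF(clamp(sim$dark_frame / scale, 0, 1), pd,
                  bits.per.sample = 16L)
  c(paths, pd)
}
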