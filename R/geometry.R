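#' Rolling-cell geometry
#'
#' Describes the simulated cell: a sphere of diameter `diameter` rolling
#' along +x (the flow direction) about a rotation axis parallel to y, with
#' bright intracellular scatterers at fixed positions in the cell frame.
#'
#' Coordinates are cell-centered micrometers: x along flow, y transverse
#' (the rotation axis), z along the optical axis. A scatterer at
#' `(x, y, z)` projects onto the image plane at x-offset
#' \eqn{R\cos(\theta + \phi)} where \eqn{R = \sqrt{x^2 + z^2}} is its radial
#' distance in the rolling plane and \eqn{\phi = \mathrm{atan2}(z, x)} its
#' phase; its y-offset stays constant while the cell rolls on-axis.
#'
#' @param diameter Cell diameter d in micrometers (> 0).
#' @param spots Numeric matrix (n x 3) of scatterer positions (x, y, z) in
#'   micrometers relative to the cell center; every spot must lie strictly
#'   inside the sphere.
#' @return An object of class `cell_geometry` with fields `diameter`,
#'   `radius`, `spots`, and derived per-spot `R`, `phi`, `y`.
#' @examples
#' geom <- cell_geometry(14, spots = cbind(x = 5, y = 0, z = 0))
#' geom$spot_R # 5
#' @export
cell_geometry <- function(diameter = 14, spots = NULL) {
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter <= 0) {
    stop("diameter must be a single positive number (um)")
  }
  if (is.null(spots)) {
    spots <- matrix(numeric(0), ncol = 3)
  }
  spots <- as.matrix(spots)
  if (ncol(spots) != 3L) stop("spots must be an n x 3 matrix (x, y, z) in um")
  r <- diameter / 2
  if (nrow(spots) > 0L) {
    rad <- sqrt(rowSums(spots^2))
    if (any(rad >= r)) {
      stop("all spots must lie strictly inside the sphere (|pos| < d/2 = ",
           r, " um); offending radial distances: ",
           paste(signif(rad[rad >= r], 4), collapse = ", "))
    }
  }
  structure(list(
    diameter = diameter,
    radius = r,
    spots = spots,
    spot_R = if (nrow(spots) > 0L) sqrt(spots[, 1]^2 + spots[, 3]^2) else numeric(0),
    spot_phi = if (nrow(spots) > 0L) atan2(spots[, 3], spots[, 1]) else numeric(0),
    spot_y = if (nrow(spots) > 0L) spots[, 2] else numeric(0)
  ), class = "cell_geometry")
}

#' Imaging parameters for the synthetic dark-field movie
#'
#' Defaults reflect a typical rolling-adhesion recording: 30 frames per
#' second and 0.53 um/px (25x magnification onto a 16-um-pixel EMCCD).
#'
#' @param pixel_size Micrometers per pixel (> 0).
#' @param frame_interval Seconds between frames (> 0).
#' @param image_shape Integer `c(ny, nx)` in pixels, or `NULL` to size the
#'   frame automatically from the simulated trajectory.
#' @param psf_sigma Gaussian PSF sigma in micrometers (> 0).
#' @param background_level Constant background intensity (arbitrary units).
#' @param gaussian_sd SD of additive Gaussian read noise (0 = noise-free).
#' @param poisson_scale If > 0, frames are Poisson-resampled with this
#'   photon-per-unit scale (0 = off).
#' @param cell_body_level,rim_level,spot_amplitude Rendering intensities for
#'   the dim cell body disk, its brighter rim, and the scatterer peaks.
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(pixel_size = 0.53, frame_interval = 1 / 30,
                           image_shape = NULL, psf_sigma = 0.6,
                           background_level = 10, gaussian_sd = 0,
                           poisson_scale = 0, cell_body_level = 20,
                           rim_level = 40, spot_amplitude = 200) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (psf_sigma <= 0) stop("psf_sigma must be > 0")
  if (!is.null(image_shape)) {
    image_shape <- as.integer(image_shape)
    stopifnot(length(image_shape) == 2L, all(image_shape > 0L))
  }
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 image_shape = image_shape, psf_sigma = psf_sigma,
                 background_level = background_level,
                 gaussian_sd = gaussian_sd, poisson_scale = poisson_scale,
                 cell_body_level = cell_body_level, rim_level = rim_level,
                 spot_amplitude = spot_amplitude),
            class = "imaging_params")
}
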