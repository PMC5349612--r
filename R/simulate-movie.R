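# Synthetic rolling-cell movies with known rotational ground truth.

in_any_interval <- function(t, intervals) {
  if (is.null(intervals) || length(intervals) == 0L) return(FALSE)
  for (iv in intervals) if (t >= iv[1] && t < iv[2]) return(TRUE)
  FALSE
}

#' Simulate the rolling dynamics of a single cell
#'
#' Integrates the kinematics that every downstream analysis tries to
#' recover. While the cell maintains traction, the rotation angle advances
#' at \eqn{d\theta/dt = 1/\tau(\theta \bmod 2\pi)} and the cell translates
#' by \eqn{dx = r\,d\theta} (pure rolling, v = r omega). During a
#' detachment interval the cell is convected faster than it rolls: the
#' translational speed is `detach_speed_factor` times the cycle-average
#' rolling speed while the rotation per distance drops to
#' `detach_ratio` (so \eqn{r\,d\theta/dx =} `detach_ratio`, <= 0.5).
#'
#' @param profile An [adhesion_profile()] (ground-truth dwell).
#' @param geometry A [cell_geometry()].
#' @param frame_interval Sampling interval in seconds.
#' @param n_cycles Number of full rotations to simulate (>= 1).
#' @param detachment_intervals List of `c(t_start, t_end)` in seconds, or
#'   `NULL`.
#' @param detach_ratio Rotation per distance (r dtheta/dx) while detached;
#'   must be <= 0.5 to be distinguishable from rolling.
#' @param detach_speed_factor Translational speed during detachment as a
#'   multiple of the cycle-average rolling speed.
#' @param substeps Euler sub-steps per frame interval.
#' @return A data.frame with columns `frame`, `t`, `theta` (cumulative rad),
#'   `x` (um), `omega` (rad/s), `v` (um/s), `detached` (logical); attribute
#'   `circumference` = pi d.
#' @export
simulate_rolling_dynamics <- function(profile, geometry,
                                      frame_interval = 1 / 30,
                                      n_cycles = 4,
                                      detachment_intervals = NULL,
                                      detach_ratio = 0.3,
                                      detach_speed_factor = 3,
                                      substeps = 20L) {
  stopifnot(inherits(profile, "adhesion_profile"),
            inherits(geometry, "cell_geometry"))
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (detach_ratio > 0.5) {
    stop("detach_ratio must be <= 0.5 (rotation per distance while floating)")
  }
  r <- geometry$radius
  v_ref <- r * profile_mean_omega(profile)
  dt <- frame_interval / substeps
  theta_target <- 2 * pi * n_cycles

  t <- 0; theta <- 0; x <- 0
  rows_t <- numeric(0); rows_theta <- numeric(0); rows_x <- numeric(0)
  rows_det <- logical(0)
  k <- 0L
  max_steps <- 5e6
  step <- 0L
  repeat {
    if (step %% substeps == 0L) {
      rows_t <- c(rows_t, t); rows_theta <- c(rows_theta, theta)
      rows_x <- c(rows_x, x)
      rows_det <- c(rows_det, in_any_interval(t, detachment_intervals))
      k <- k + 1L
    }
    if (theta >= theta_target) break
    detached <- in_any_interval(t, detachment_intervals)
    if (detached) {
      v <- detach_speed_factor * v_ref
      dx <- v * dt
      dth <- detach_ratio * dx / r
    } else {
      dth <- dt / profile_dwell(profile, theta)
      dx <- r * dth
    }
    theta <- theta + dth; x <- x + dx; t <- t + dt
    step <- step + 1L
    if (step > max_steps) stop("dynamics integration did not terminate")
  }
  n <- length(rows_t)
  omega <- c(NA, diff(rows_theta)) / frame_interval
  omega[1] <- omega[2]
  v <- c(NA, diff(rows_x)) / frame_interval
  v[1] <- v[2]
  out <- data.frame(frame = seq_len(n), t = rows_t, theta = rows_theta,
                    x = rows_x, omega = omega, v = v, detached = rows_det)
  attr(out, "circumference") <- pi * geometry$diameter
  out
}

# Render one dark-field frame: dim disk + bright rim + Gaussian scatterers.
# cx, cy: cell center in um; theta: rotation angle. Coordinates: column j
# center at (j - 0.5) * px um (x), row i center at (i - 0.5) * px um (y).
render_frame <- function(ny, nx, px, cx, cy, theta, geometry, imaging,
                         depth_modulation = FALSE) {
  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px
  frame <- matrix(imaging$background_level, ny, nx)
  r <- geometry$radius
  dx2 <- outer(rep(1, ny), (xs - cx)^2)
  dy2 <- outer((ys - cy)^2, rep(1, nx))
  rho <- sqrt(dx2 + dy2)
  frame <- frame + imaging$cell_body_level * (rho < r)
  rim_sigma <- max(0.4, px / 2)
  frame <- frame + imaging$rim_level * exp(-(rho - r)^2 / (2 * rim_sigma^2))
  ns <- length(geometry$spot_R)
  if (ns > 0L) {
    s2 <- 2 * imaging$psf_sigma^2
    for (s in seq_len(ns)) {
      sx <- cx + geometry$spot_R[s] * cos(theta + geometry$spot_phi[s])
      sy <- cy + geometry$spot_y[s]
      amp <- imaging$spot_amplitude
      if (depth_modulation) {
        # scatterer on the far (z < 0) side rendered dimmer
        depth <- -geometry$spot_R[s] * sin(theta + geometry$spot_phi[s])
        amp <- amp * (0.6 + 0.4 * (depth + r) / (2 * r))
      }
      gx <- exp(-(xs - sx)^2 / s2)
      gy <- exp(-(ys - sy)^2 / s2)
      frame <- frame + amp * outer(gy, gx)
    }
  }
  frame
}

#' Simulate a dark-field movie of a rolling cell
#'
#' Renders the dynamics of [simulate_rolling_dynamics()] into a TIFF-ready
#' grayscale stack: the cell body as a dim disk with a brighter rim, each
#' intracellular scatterer as a Gaussian of the PSF width at its projected
#' position \eqn{x_{cell} + R\cos(\theta+\phi)}, plus optional Gaussian and
#' Poisson noise.
#'
#' @inheritParams simulate_rolling_dynamics
#' @param imaging An [imaging_params()].
#' @param seed Integer seed; the generator is fully reproducible.
#' @param depth_modulation Dim scatterers on the far side of the cell
#'   (off by default).
#' @param margin_um Blank margin around the trajectory when the frame is
#'   auto-sized.
#' @return A list of class `rolling_movie`: `movie` (array ny x nx x nframes),
#'   `truth` (ground-truth list: per-frame dynamics, spot table, detachment
#'   intervals, circumference), `imaging`, `geometry`, `profile`.
#' @export
simulate_rolling_movie <- function(profile, geometry, imaging = imaging_params(),
                                   detachment_intervals = NULL, n_cycles = 4,
                                   seed = 1L, detach_ratio = 0.3,
                                   detach_speed_factor = 3,
                                   depth_modulation = FALSE, margin_um = 4) {
  stopifnot(inherits(imaging, "imaging_params"))
  set.seed(seed)
  dyn <- simulate_rolling_dynamics(profile, geometry,
                                   frame_interval = imaging$frame_interval,
                                   n_cycles = n_cycles,
                                   detachment_intervals = detachment_intervals,
                                   detach_ratio = detach_ratio,
                                   detach_speed_factor = detach_speed_factor)
  px <- imaging$pixel_size
  r <- geometry$radius
  x0 <- margin_um + r            # cell center x at t = 0
  y_extent <- 2 * (r + margin_um)
  x_extent <- x0 + max(dyn$x) + r + margin_um
  need_nx <- as.integer(ceiling(x_extent / px))
  need_ny <- as.integer(ceiling(y_extent / px))
  if (is.null(imaging$image_shape)) {
    ny <- need_ny; nx <- need_nx
  } else {
    ny <- imaging$image_shape[1]; nx <- imaging$image_shape[2]
    if (ny < need_ny || nx < need_nx) {
      stop("movie would exceed image bounds; required image_shape is at least c(",
           need_ny, ", ", need_nx, ") px")
    }
  }
  cy <- ny * px / 2
  nf <- nrow(dyn)
  movie <- array(0, dim = c(ny, nx, nf))
  for (f in seq_len(nf)) {
    fr <- render_frame(ny, nx, px, x0 + dyn$x[f], cy, dyn$theta[f],
                       geometry, imaging, depth_modulation)
    if (imaging$gaussian_sd > 0) {
      fr <- fr + matrix(stats::rnorm(ny * nx, sd = imaging$gaussian_sd), ny, nx)
    }
    if (imaging$poisson_scale > 0) {
      fr <- matrix(stats::rpois(ny * nx, pmax(fr, 0) * imaging$poisson_scale),
                   ny, nx) / imaging$poisson_scale
    }
    movie[, , f] <- fr
  }
  truth <- list(
    frames = transform(dyn, x_world = x0 + dyn$x, y_world = cy),
    spots = data.frame(R = geometry$spot_R, phi = geometry$spot_phi,
                       y = geometry$spot_y),
    detachment_intervals = detachment_intervals,
    circumference = pi * geometry$diameter,
    seed = seed
  )
  structure(list(movie = movie, truth = truth, imaging = imaging,
                 geometry = geometry, profile = profile),
            class = "rolling_movie")
}

#' Simulate a population of rolling cells (dynamics level)
#'
#' Draws a cohort of cells with normally distributed diameters, random
#' patchy adhesion profiles (1-3 additive patches of width pi/6 to 5pi/6
#' and dwell multiplier 2-8, matching the range of patch sizes seen on
#' rolling leukocytes) and random transient detachments (a Poisson number
#' of events at `detach_rate_per_cycle`, each lasting 1-2.5 s, during
#' which the cell is convected at `detach_speed_factor` times its rolling
#' speed with rotation per distance `detach_ratio`), then integrates each
#' cell's rolling dynamics. This is the harness for population-level
#' comparisons of angle-based versus position-based dwell analysis.
#'
#' @param n_cells Number of cells (default 30).
#' @param diameter_mean,diameter_sd Cell diameter distribution in um.
#' @param baseline_dwell Baseline dwell in s/rad.
#' @param n_cycles Rotation cycles per cell.
#' @param frame_interval Sampling interval (s).
#' @param detach_rate_per_cycle Mean detachment events per rotation cycle.
#' @param detach_duration Range (s) of detachment durations.
#' @param detach_speed_factor,detach_ratio Passed to
#'   [simulate_rolling_dynamics()].
#' @param patch_width,patch_multiplier Ranges for the random patches.
#' @param seed Integer seed.
#' @return List of cells; each has `dynamics` (data.frame from
#'   [simulate_rolling_dynamics()]), `profile`, `geometry`, `diameter`,
#'   `detachment_intervals`.
#' @export
simulate_rolling_population <- function(n_cells = 30, diameter_mean = 14.1,
                                        diameter_sd = 1.0,
                                        baseline_dwell = 0.3, n_cycles = 10,
                                        frame_interval = 1 / 30,
                                        detach_rate_per_cycle = 0.6,
                                        detach_duration = c(1.0, 2.5),
                                        detach_speed_factor = 5,
                                        detach_ratio = 0.3,
                                        patch_width = c(pi / 6, 5 * pi / 6),
                                        patch_multiplier = c(2, 8),
                                        seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_cells), function(i) {
    d <- stats::rnorm(1, diameter_mean, diameter_sd)
    d <- max(d, diameter_mean - 3 * diameter_sd, 8)
    np <- sample(1:3, 1)
    prof <- adhesion_profile(
      data.frame(center = stats::runif(np, 0, 2 * pi),
                 width = stats::runif(np, patch_width[1], patch_width[2]),
                 multiplier = stats::runif(np, patch_multiplier[1],
                                           patch_multiplier[2])),
      baseline_dwell)
    geom <- cell_geometry(d)
    T_est <- n_cycles * 2 * pi / profile_mean_omega(prof)
    nd <- stats::rpois(1, detach_rate_per_cycle * n_cycles)
    det <- NULL
    if (nd > 0) {
      starts <- sort(stats::runif(nd, 0.05, 0.9)) * T_est
      det <- lapply(starts, function(t0)
        c(t0, t0 + stats::runif(1, detach_duration[1], detach_duration[2])))
    }
    dyn <- simulate_rolling_dynamics(prof, geom, frame_interval, n_cycles,
                                     det, detach_ratio = detach_ratio,
                                     detach_speed_factor = detach_speed_factor)
    list(dynamics = dyn, profile = prof, geometry = geom, diameter = d,
         detachment_intervals = det)
  })
}

#' Write a movie stack as a multi-page TIFF
#'
#' Intensities are scaled into \[0, 1\] by a fixed `scale` (default: the
#' stack maximum) so pages share one calibration.
#'
#' @param movie 3D array (ny x nx x nframes) or `rolling_movie`.
#' @param path Output path.
#' @param scale Intensity mapped to white; defaults to the stack maximum.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, scale = NULL) {
  if (inherits(movie, "rolling_movie")) movie <- movie$movie
  stopifnot(length(dim(movie)) == 3L)
  scale <- scale %||% max(movie)
  pages <- lapply(seq_len(dim(movie)[3]),
                  function(f) clamp(movie[, , f] / scale, 0, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a movie stack
#'
#' @param path TIFF path.
#' @return 3D array ny x nx x nframes.
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Write ground truth as JSON
#'
#' @param truth The `truth` element of a simulator result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
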