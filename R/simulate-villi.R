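# Monte-Carlo model of randomly distributed microvilli making contact
# during rolling. Used to test whether random placement alone can produce
# large adhesion patches.

#' Simulate microvilli contacts of a rolling sphere
#'
#' Microvilli are placed uniformly at random on the sphere surface
#' (area-uniform). The sphere rolls about a fixed axis (y); a microvillus
#' can form a tether once per rotation cycle, when it sweeps through the
#' contact region at the bottom of the sphere. Contact requires (i) band
#' membership -- distance from the rolling plane at most half the band
#' width (|y| <= band_width/2) -- and (ii) passage through the contact
#' arc, of half-length (band_width/2)/r around bottom dead center
#' (circular contact patch of diameter equal to the band width). Each
#' tether is recorded in the angular bin at which the microvillus enters
#' the contact arc. After placement the geometry is deterministic, so
#' per-bin counts are identical across cycles.
#'
#' @param geometry A [cell_geometry()].
#' @param n_villi Number of microvilli on the cell (default 730).
#' @param receptors_per_villus Adhesion receptors per microvillus tip
#'   (default 17); weights the expected footprint.
#' @param band_width Contact band width in um (< cell diameter).
#' @param n_cycles Number of rotation cycles to tabulate.
#' @param bin_width Angular bin width in rad. If it does not divide 2*pi
#'   evenly the last bin is truncated and flagged in the output.
#' @param seed Integer seed for villi placement.
#' @param footprint_pixel um per pixel of the expected-footprint grid.
#' @return Object of class `contact_census`: villi table, `bin_edges`,
#'   `tether_counts` (bins x cycles matrix), `truncated_last_bin`,
#'   `expected_footprint` (receptor-weighted event map over one period),
#'   and the simulation parameters.
#' @export
simulate_microvilli_contacts <- function(geometry, n_villi = 730,
                                         receptors_per_villus = 17,
                                         band_width = 5.7, n_cycles = 3,
                                         bin_width = 2 * pi / 18, seed = 1L,
                                         footprint_pixel = 0.5) {
  stopifnot(inherits(geometry, "cell_geometry"))
  if (n_villi < 1) stop("n_villi must be >= 1")
  r <- geometry$radius
  if (band_width >= geometry$diameter) {
    stop("band_width must be smaller than the cell diameter")
  }
  set.seed(seed)
  # area-uniform placement: y uniform in [-r, r], azimuth uniform
  y <- stats::runif(n_villi, -r, r)
  phi <- stats::runif(n_villi, 0, 2 * pi)
  in_band <- abs(y) <= band_width / 2
  # villus is at bottom dead center when theta + phi = pi/2 (mod 2pi);
  # it enters the contact arc half an arc earlier
  arc_half <- (band_width / 2) / r
  theta_bottom <- wrap_2pi(pi / 2 - phi)
  theta_entry <- wrap_2pi(theta_bottom - arc_half)

  n_full <- as.integer(floor(2 * pi / bin_width + 1e-9))
  truncated <- (2 * pi - n_full * bin_width) > 1e-9
  edges <- seq(0, by = bin_width, length.out = n_full + 1L)
  if (truncated) edges <- c(edges, 2 * pi)
  n_bins <- length(edges) - 1L
  counts_one <- as.vector(table(cut(theta_entry[in_band], breaks = edges,
                                    include.lowest = TRUE, right = FALSE)))
  tether_counts <- matrix(rep(counts_one, n_cycles), ncol = n_cycles)
  rownames(tether_counts) <- NULL

  # expected footprint over one rolling period: event at x = r * theta_bottom
  nxp <- max(1L, as.integer(ceiling(pi * geometry$diameter / footprint_pixel)))
  nyp <- max(1L, as.integer(ceiling(band_width / footprint_pixel)))
  grid <- matrix(0, nyp, nxp)
  bx <- clamp(as.integer(floor(r * theta_bottom[in_band] / footprint_pixel)) + 1L,
              1L, nxp)
  by <- clamp(as.integer(floor((y[in_band] + band_width / 2) / footprint_pixel)) + 1L,
              1L, nyp)
  for (i in seq_along(bx)) {
    grid[by[i], bx[i]] <- grid[by[i], bx[i]] + receptors_per_villus
  }

  structure(list(
    n_villi = n_villi,
    receptors_per_villus = receptors_per_villus,
    band_width = band_width,
    geometry = geometry,
    villi = data.frame(y = y, phi = phi, in_band = in_band,
                       theta_entry = theta_entry),
    bin_edges = edges,
    truncated_last_bin = truncated,
    tether_counts = tether_counts,
    expected_footprint = list(grid = grid, pixel = footprint_pixel),
    seed = seed
  ), class = "contact_census")
}

#' Mean number of microvilli in instantaneous contact
#'
#' Counts, averaged over the rotation phase, the microvilli inside a
#' circular contact patch of the given area at the bottom of the sphere.
#' For area-uniform placement this converges to
#' `n_villi * contact_area / (pi d^2)` (the cap-area fraction of the
#' sphere surface pi d^2).
#'
#' @param census A `contact_census`.
#' @param contact_area Contact patch area in um^2.
#' @param n_phases Rotation phases to average over.
#' @return Mean count (numeric scalar).
#' @export
mean_instantaneous_contact <- function(census, contact_area, n_phases = 180L) {
  stopifnot(inherits(census, "contact_census"))
  r <- census$geometry$radius
  # spherical cap of area A: A = 2 pi r^2 (1 - cos psi)
  cos_psi <- 1 - contact_area / (2 * pi * r^2)
  if (cos_psi <= -1) stop("contact_area exceeds the sphere surface")
  v <- census$villi
  rho <- sqrt(pmax(r^2 - v$y^2, 0))
  phases <- (seq_len(n_phases) - 1L) * 2 * pi / n_phases
  counts <- vapply(phases, function(th) {
    # villus position z-component toward substrate: -rho*sin(th + phi);
    # angular distance from bottom point has cosine rho*sin(th+phi)/r
    sum(rho * sin(th + v$phi) / r >= cos_psi)
  }, numeric(1))
  mean(counts)
}
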