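# Periodicity and contact geometry of adhesion-footprint tracks.

#' 2D cross-correlation of a footprint track with a repeating unit
#'
#' Zero-normalized cross-correlation of a single repeating unit against the
#' whole track image. Local maxima of the correlation profile along x
#' (above `threshold`, separated by at least `min_separation_px`) mark the
#' repeats; the period is the median spacing between consecutive peaks.
#'
#' @param track_image Matrix: the isolated track (long axis = x = columns).
#' @param unit_image Matrix: one repeating unit, strictly smaller than the
#'   track image.
#' @param pixel_size um per pixel.
#' @param threshold Minimum correlation for a peak (default 0.3).
#' @param min_separation_px Minimum peak spacing; defaults to half the unit
#'   width.
#' @return List of class `track_xcorr`: `map` (correlation matrix),
#'   `profile` (max over y per x offset), `peak_x_px` (unit-center column
#'   positions in the track image), `period_px`, `period_um`.
#' @export
track_cross_correlation <- function(track_image, unit_image, pixel_size = 1,
                                    threshold = 0.3,
                                    min_separation_px = NULL) {
  if (nrow(unit_image) > nrow(track_image) ||
      ncol(unit_image) > ncol(track_image)) {
    stop("unit_image must be smaller than track_image")
  }
  map <- zncc(track_image, unit_image)
  profile <- apply(map, 2, max)
  min_sep <- min_separation_px %||% (ncol(unit_image) %/% 2L)
  cand <- local_maxima(profile, min_value = threshold)
  # enforce minimum separation, keeping the strongest peaks first
  cand <- cand[order(-profile[cand])]
  sel <- integer(0)
  for (i in cand) {
    if (all(abs(i - sel) >= min_sep)) sel <- c(sel, i)
  }
  sel <- sort(sel)
  centers <- sel + (ncol(unit_image) - 1) / 2
  period_px <- if (length(sel) >= 2L) stats::median(diff(sel)) else NA_real_
  structure(list(map = map, profile = profile, peak_x_px = centers,
                 period_px = period_px,
                 period_um = period_px * pixel_size,
                 pixel_size = pixel_size),
            class = "track_xcorr")
}

#' Average the footprint over single periods
#'
#' Crops full-height windows of width `period_px` centered on the detected
#' repeat positions and averages them pixelwise -- the mean single-period
#' (0 to 2 pi) adhesion image. Windows extending past the track ends are
#' excluded and counted. The normalized copy maps background (minimum) to 0
#' and maximum to 1 for contour display.
#'
#' @param track_image Matrix.
#' @param period_px Period in px (from [track_cross_correlation()]).
#' @param peak_positions Unit-center column positions (px).
#' @return List: `unit_mean`, `normalized`, `n_used`, `n_excluded`.
#' @export
average_period_unit <- function(track_image, period_px, peak_positions) {
  w <- as.integer(round(period_px))
  if (w < 2L) stop("period too short")
  nx <- ncol(track_image)
  crops <- list(); n_excl <- 0L
  for (cpos in peak_positions) {
    c0 <- as.integer(round(cpos - (w - 1) / 2))   # window start from center
    c1 <- c0 + w - 1L
    if (c0 < 1L || c1 > nx) { n_excl <- n_excl + 1L; next }
    crops[[length(crops) + 1L]] <- track_image[, c0:c1, drop = FALSE]
  }
  if (length(crops) < 2L) {
    stop("need at least 2 complete periods; got ", length(crops),
         " (", n_excl, " excluded at track ends)")
  }
  unit_mean <- Reduce(`+`, crops) / length(crops)
  bg <- min(unit_mean)
  normalized <- (unit_mean - bg) / (max(unit_mean) - bg)
  list(unit_mean = unit_mean, normalized = normalized,
       n_used = length(crops), n_excluded = n_excl)
}

#' 1D autocorrelation of a footprint track along the flow axis
#'
#' Sums the track band transversely into a 1D intensity profile, applies
#' the mean-subtracted normalized autocorrelation along x, and reports the
#' lag axis both in micrometers and normalized by the rolling circumference
#' \eqn{\pi d}, where the repeat of a rolling cell's footprint is expected
#' at normalized lag 1.
#'
#' @param track_image Matrix (isolated track band).
#' @param diameter Cell diameter d in um (> 0).
#' @param pixel_size um per pixel.
#' @param band_rows Optional integer rows to sum over (default: all rows).
#' @param max_lag_frac Maximum lag as a fraction of the track length.
#' @param min_height Minimum autocorrelation value for a reported peak.
#' @return A `periodicity_result` with `lag` normalized by pi*d (units
#'   `"circumference"`), plus fields `lag_um` and `period_um`.
#' @export
footprint_autocorrelation <- function(track_image, diameter, pixel_size,
                                      band_rows = NULL, max_lag_frac = 0.8,
                                      min_height = 0.1) {
  if (diameter <= 0) stop("diameter must be > 0")
  rows <- band_rows %||% seq_len(nrow(track_image))
  if (length(rows) < 3L) stop("track band narrower than 3 px")
  prof <- colSums(track_image[rows, , drop = FALSE])
  nlag <- floor(max_lag_frac * (length(prof) - 1L))
  rho <- acf_biased(prof, nlag)
  period_norm <- pi * diameter / pixel_size        # expected period in px
  res <- periodicity_result(lag = (0:nlag) / period_norm, acf_vals = rho,
                            period_nominal = 1, units = "circumference",
                            window_frac = 0.15, min_height = min_height)
  res$lag_um <- (0:nlag) * pixel_size
  res$period_um <- res$period * pi * diameter
  res
}

#' Contact width of a footprint track
#'
#' Transverse (y) mean intensity profile of the track; the width is the
#' extent over which the profile exceeds background by the larger of
#' `k` noise SDs and half the profile's peak height above background
#' (background and noise SD estimated from the flanking rows). The
#' half-peak floor makes the crossing sit at the band edge of a blurred
#' top-hat regardless of the optical blur.
#'
#' @param track_image Matrix containing one track, roughly centered.
#' @param pixel_size um per pixel.
#' @param k Noise-SD multiplier (default 3).
#' @param flank_rows Rows at each transverse edge used for background.
#' @return Width in um; attributes `threshold`, `rows` (first/last above
#'   threshold).
#' @export
contact_width <- function(track_image, pixel_size, k = 3, flank_rows = 5L) {
  p <- rowMeans(track_image)
  ny <- length(p)
  if (ny < 2L * flank_rows + 3L) stop("image too small for flanking background")
  flank <- c(seq_len(flank_rows), (ny - flank_rows + 1L):ny)
  bg <- mean(p[flank])
  noise <- stats::sd(p[flank])
  peak <- max(p)
  if (peak <= bg) stop("profile never exceeds background; no track found")
  thr <- bg + max(k * noise, 0.5 * (peak - bg))
  above <- which(p > thr)
  if (length(above) == 0L) stop("profile never exceeds the threshold")
  width <- (above[length(above)] - above[1] + 1L) * pixel_size
  attr(width, "threshold") <- thr
  attr(width, "rows") <- c(above[1], above[length(above)])
  width
}

#' Contact area and surface fraction from the contact width
#'
#' Assuming a circular contact patch of diameter equal to the measured
#' contact width w, the contact area is \eqn{\pi (w/2)^2} and the fraction
#' of the total sphere surface (\eqn{\pi d^2}) is \eqn{100\,A/(\pi d^2)}
#' percent.
#'
#' @param width Contact width in um (> 0, < diameter).
#' @param diameter Cell diameter in um.
#' @return List: `area_um2`, `fraction_pct`.
#' @examples
#' contact_geometry(5.7, 14.1) # ~26 um^2, ~4 %
#' @export
contact_geometry <- function(width, diameter) {
  if (width <= 0 || diameter <= 0) stop("width and diameter must be > 0")
  if (width >= diameter) {
    stop("contact width (", width, ") must be smaller than the diameter (",
         diameter, "); geometry invalid")
  }
  area <- pi * (width / 2)^2
  list(area_um2 = area, fraction_pct = 100 * area / (pi * diameter^2))
}

#' Isolate the track band(s) of a footprint mosaic
#'
#' Footprint tracks run along the flow (x) axis, so each track appears as a
#' contiguous band of rows whose mean intensity rises above background. The
#' transverse profile of a Gaussian-smoothed copy of the mosaic is
#' thresholded at background plus a fraction of the peak height; each
#' contiguous run of above-threshold rows wider than `min_width_um` becomes
#' one ROI (padded, full x range). Bands that touch after padding (tracks
#' crossing or overlapping) are dropped, mirroring the practice of
#' analysing only isolated tracks.
#'
#' @param mosaic Matrix.
#' @param pixel_size um per pixel.
#' @param smooth_sigma_um Smoothing sigma in um.
#' @param min_width_um Minimum transverse band width.
#' @param rel_threshold Fraction of (peak - background) above background.
#' @param pad_um Padding added around each band (clipped to the image).
#' @return List of ROIs, each a list with `rows`, `cols` (integer ranges).
#' @export
isolate_track_roi <- function(mosaic, pixel_size, smooth_sigma_um = 1,
                              min_width_um = 1.5, rel_threshold = 0.25,
                              pad_um = 2) {
  s_px <- max(1, smooth_sigma_um / pixel_size)
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(mosaic),
                                          sigma = s_px))
  p <- rowMeans(sm)
  bg <- stats::median(p)
  pk <- max(p)
  if (pk <= bg) return(list())
  above <- p > bg + rel_threshold * (pk - bg)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  pad <- as.integer(round(pad_um / pixel_size))
  rois <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    if (runs$lengths[k] * pixel_size < min_width_um) next
    rois[[length(rois) + 1L]] <- list(
      rows = max(1L, starts[k] - pad):min(nrow(mosaic), ends[k] + pad),
      cols = seq_len(ncol(mosaic)))
  }
  # drop bands that touch after padding (crossing / overlapping tracks)
  if (length(rois) > 1L) {
    keep <- rep(TRUE, length(rois))
    for (i in seq_along(rois)) {
      for (j in seq_along(rois)) {
        if (i != j &&
            length(intersect(rois[[i]]$rows, rois[[j]]$rows)) > 0L) {
          keep[i] <- FALSE
        }
      }
    }
    rois <- rois[keep]
  }
  rois
}

#' Periodicity prevalence in percent
#'
#' Share of analysed footprint tracks that exhibit periodicity, as printed
#' in a report stage summary.
#'
#' @param n_periodic Number of periodic tracks.
#' @param n_total Total number of tracks (> 0).
#' @return Percentage (0-100).
#' @examples
#' prevalence_pct(51, 63) # ~81
#' @export
prevalence_pct <- function(n_periodic, n_total) {
  if (n_total <= 0) stop("n_total must be > 0")
  if (n_periodic < 0 || n_periodic > n_total) {
    stop("n_periodic must lie in [0, n_total]")
  }
  100 * n_periodic / n_total
}
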