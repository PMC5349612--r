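# Fluorescence footprint image corrections and tile stitching.

as_tile_list <- function(tiles) {
  if (is.array(tiles) && length(dim(tiles)) == 3L) {
    tiles <- lapply(seq_len(dim(tiles)[3]), function(k) tiles[, , k])
  }
  stopifnot(is.list(tiles), length(tiles) >= 1L)
  tiles
}

#' Estimate the normalized illumination profile
#'
#' Pixelwise mean of background-subtracted images \eqn{\langle I_0 - I_{bg}
#' \rangle}, optionally Gaussian-smoothed, scaled by its maximum so the
#' profile has max exactly 1. Works because the sparse fluorescent signal
#' averages out over many tiles, leaving the fixed illumination field.
#'
#' @param tiles List of matrices (or 3D array) sharing one illumination
#'   field.
#' @param dark_frame Background image without illumination (matrix or
#'   scalar; default 0).
#' @param smooth_sigma_px Gaussian smoothing sigma in px applied before
#'   normalization (0 = none).
#' @return Matrix with values in (0, 1\], max exactly 1.
#' @export
estimate_illumination <- function(tiles, dark_frame = 0, smooth_sigma_px = 0) {
  tiles <- as_tile_list(tiles)
  if (length(tiles) < 2L) {
    warning("illumination estimated from a single image; profile equals ",
            "that image normalized")
  }
  acc <- Reduce(`+`, lapply(tiles, function(t) t - dark_frame)) / length(tiles)
  if (smooth_sigma_px > 0) {
    acc <- EBImage::imageData(EBImage::gblur(EBImage::Image(acc),
                                             sigma = smooth_sigma_px))
  }
  mx <- max(acc)
  if (mx <= 0) stop("illumination estimate has non-positive maximum; no signal")
  acc / mx
}

#' Flat-field correction of a fluorescence image
#'
#' \eqn{I_{corrected} = (I_0 - I_{bg}) / I_{illumination}}. Pixels where the
#' illumination profile falls below `eps` are masked (set to 0) and counted.
#'
#' @param I0 Raw image (matrix).
#' @param Ibg Background image or scalar (default 0).
#' @param illum Normalized illumination profile (matrix or scalar 1).
#' @param eps Illumination floor below which pixels are masked.
#' @return Corrected matrix; attributes `n_masked` and `mask` (logical
#'   matrix) when any pixel was masked.
#' @export
correct_illumination <- function(I0, Ibg = 0, illum = 1, eps = 1e-3) {
  if (is.matrix(Ibg) && !all(dim(Ibg) == dim(I0))) {
    stop("Ibg dimensions do not match I0")
  }
  if (is.matrix(illum) && !all(dim(illum) == dim(I0))) {
    stop("illum dimensions do not match I0")
  }
  low <- illum < eps
  out <- (I0 - Ibg) / pmax(illum, eps)
  if (any(low)) {
    if (length(low) == 1L) low <- matrix(TRUE, nrow(I0), ncol(I0))
    out[low] <- 0
    attr(out, "n_masked") <- sum(low)
    attr(out, "mask") <- low
  }
  out
}

# correlation score of tile k against tile k+1 for a candidate placement:
# tile2 at column offset `stride` and row offset `dy` relative to tile1
overlap_correlation <- function(tile1, tile2, stride, dy) {
  ny <- nrow(tile1); tw <- ncol(tile1)
  ow <- tw - stride
  if (ow < 4L) return(NA_real_)
  r1 <- max(1L, 1L + dy):min(ny, ny + dy)
  r2 <- r1 - dy
  if (length(r1) < 8L) return(NA_real_)
  a <- tile1[r1, (stride + 1L):tw, drop = FALSE]
  b <- tile2[r2, seq_len(ow), drop = FALSE]
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(NA_real_)
  stats::cor(as.vector(a), as.vector(b))
}

#' Stitch overlapping image tiles into a mosaic
#'
#' Integer pixel offsets between adjacent tiles are estimated by maximizing
#' the normalized cross-correlation of their overlap strips over a small
#' search window around the nominal overlap. Tiles are then cropped and
#' joined without blending or averaging (each seam keeps the later tile's
#' pixels). If the best correlation for a pair falls below `min_corr`
#' (featureless overlap), the nominal offset is used and the pair flagged.
#'
#' @param tiles List of matrices (or 3D array), ordered along the x axis.
#' @param nominal_overlap_px Nominal overlap in px (>= 8).
#' @param search Search half-window in px around the nominal offset.
#' @param min_corr Correlation below which the nominal offset is used.
#' @return List of class `mosaic`: `mosaic` (matrix), `offsets` (data.frame
#'   `tile`, `x_px`, `y_px` 0-based placement offsets, `corr`, `fallback`).
#' @export
stitch_tiles <- function(tiles, nominal_overlap_px, search = 5L,
                         min_corr = 0.5) {
  tiles <- as_tile_list(tiles)
  if (nominal_overlap_px < 8L) stop("overlap must be at least 8 px")
  n <- length(tiles)
  ny <- nrow(tiles[[1]]); tw <- ncol(tiles[[1]])
  x_off <- integer(n); y_off <- integer(n)
  corr <- rep(NA_real_, n); fallback <- logical(n)
  nominal_stride <- tw - as.integer(nominal_overlap_px)
  if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      best <- c(score = -Inf, stride = nominal_stride, dy = 0L)
      for (ds in (-search):search) {
        stride <- nominal_stride + ds
        if (stride < 1L || stride >= tw) next
        for (dy in (-search):search) {
          sc <- overlap_correlation(tiles[[k]], tiles[[k + 1L]], stride, dy)
          if (is.finite(sc) && sc > best["score"]) {
            best <- c(score = sc, stride = stride, dy = dy)
          }
        }
      }
      if (!is.finite(best["score"]) || best["score"] < min_corr) {
        fallback[k + 1L] <- TRUE
        best["stride"] <- nominal_stride
        best["dy"] <- 0L
      }
      corr[k + 1L] <- best["score"]
      x_off[k + 1L] <- x_off[k] + as.integer(best["stride"])
      y_off[k + 1L] <- y_off[k] + as.integer(best["dy"])
    }
  }
  # canvas
  y0 <- min(y_off); y1 <- max(y_off)
  H <- ny + (y1 - y0)
  W <- x_off[n] + tw
  mosaic <- matrix(0, H, W)
  for (k in seq_len(n)) {
    rr <- (y_off[k] - y0 + 1L):(y_off[k] - y0 + ny)
    cc <- (x_off[k] + 1L):(x_off[k] + tw)
    mosaic[rr, cc] <- tiles[[k]]
  }
  structure(list(
    mosaic = mosaic,
    offsets = data.frame(tile = seq_len(n), x_px = x_off, y_px = y_off,
                         corr = corr, fallback = fallback)
  ), class = "mosaic")
}
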