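# Intracellular spot detection in cell-centered stacks.

# Background-subtracted intensity-weighted centroid of one labelled
# component; weights below `floor_val` are clipped to zero.
component_centroid <- function(frame, idx, floor_val) {
  w <- pmax(frame[idx] - floor_val, 0)
  if (sum(w) <= 0) w <- rep(1, length(idx))
  ri <- (idx - 1) %% nrow(frame) + 1
  ci <- (idx - 1) %/% nrow(frame) + 1
  c(x = sum(ci * w) / sum(w), y = sum(ri * w) / sum(w))
}

# MSER-style detector: sweep intensity thresholds from bright to dim,
# follow each bright core through the component tree and keep the level at
# which its area is most stable.
detect_mser_frame <- function(frame, pixel_size, n_levels, max_variation,
                              min_area, max_area, min_contrast) {
  rng <- range(frame)
  if (rng[2] - rng[1] <= 0) return(NULL)
  med <- stats::median(frame)
  madv <- stats::mad(frame)
  lo <- stats::quantile(frame, 0.60)
  thresholds <- seq(rng[2] - 0.02 * (rng[2] - rng[1]), lo,
                    length.out = n_levels) # descending
  labs <- lapply(thresholds, function(t)
    EBImage::imageData(EBImage::bwlabel(EBImage::Image((frame >= t) * 1))))
  # seeds: brightest pixel of every component, collected over all levels so
  # dimmer cores missed at the top threshold still get a chain
  seeds <- integer(0)
  for (l in seq_len(n_levels)) {
    lv <- labs[[l]]
    nl <- max(lv)
    if (nl == 0L) next
    has_seed <- if (length(seeds) > 0L) unique(lv[seeds]) else integer(0)
    for (s in seq_len(nl)) {
      if (s %in% has_seed) next
      idx0 <- which(lv == s)
      seeds <- c(seeds, idx0[which.max(frame[idx0])])
    }
  }
  if (length(seeds) == 0L) return(NULL)
  feats <- NULL
  claimed <- character(0)
  for (seed in seeds) {
    if (frame[seed] < med + min_contrast * max(madv, 1e-12)) next
    areas <- integer(n_levels)
    comp_ids <- integer(n_levels)
    for (l in seq_len(n_levels)) {
      id <- labs[[l]][seed]
      comp_ids[l] <- id
      areas[l] <- sum(labs[[l]] == id)
    }
    # stability: relative area growth across +-1 level
    v <- rep(Inf, n_levels)
    for (l in 2:(n_levels - 1L)) {
      v[l] <- (areas[l + 1L] - areas[l - 1L]) / areas[l]
    }
    ok <- which(v <= max_variation & areas >= min_area & areas <= max_area)
    if (length(ok) == 0L) next
    lstar <- ok[which.min(v[ok])]
    key <- paste(lstar, comp_ids[lstar])
    if (key %in% claimed) next       # two seeds, same stable region
    claimed <- c(claimed, key)
    idx <- which(labs[[lstar]] == comp_ids[lstar])
    cen <- component_centroid(frame, idx, thresholds[lstar])
    feats <- rbind(feats, data.frame(
      x_um = (cen["x"] - 0.5) * pixel_size,
      y_um = (cen["y"] - 0.5) * pixel_size,
      area_px = areas[lstar],
      score = -v[lstar],
      peak = frame[seed]))
  }
  feats
}

# Laplacian-of-Gaussian blob detector (alternative behind the same contract)
detect_log_frame <- function(frame, pixel_size, sigma_um, min_response) {
  s_px <- max(1, sigma_um / pixel_size)
  half <- as.integer(ceiling(3 * s_px))
  ax <- (-half):half
  g <- exp(-ax^2 / (2 * s_px^2))
  # separable LoG approximation via difference of Gaussians (1.6 ratio)
  g2 <- exp(-ax^2 / (2 * (1.6 * s_px)^2))
  k1 <- outer(g, g); k1 <- k1 / sum(k1)
  k2 <- outer(g2, g2); k2 <- k2 / sum(k2)
  pad <- half
  padded <- matrix(stats::median(frame), nrow(frame) + 2 * pad,
                   ncol(frame) + 2 * pad)
  padded[pad + seq_len(nrow(frame)), pad + seq_len(ncol(frame))] <- frame
  resp <- xcorr2_valid(padded, k1) - xcorr2_valid(padded, k2)
  madv <- stats::mad(frame)
  thr <- min_response * max(madv, 1e-12)
  ny <- nrow(resp); nx <- ncol(resp)
  feats <- NULL
  for (i in 2:(ny - 1L)) {
    for (j in 2:(nx - 1L)) {
      w <- resp[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (resp[i, j] >= thr && resp[i, j] == max(w) && sum(w == resp[i, j]) == 1L) {
        # refine with a weighted centroid on the background-subtracted patch
        r0 <- max(1L, i - half); r1 <- min(nrow(frame), i + half)
        c0 <- max(1L, j - half); c1 <- min(ncol(frame), j + half)
        patch <- frame[r0:r1, c0:c1]
        wgt <- pmax(patch - stats::median(frame), 0)
        ci <- sum(t(t(wgt) * (c0:c1))) / sum(wgt)
        ri <- sum(wgt * (r0:r1)) / sum(wgt)
        feats <- rbind(feats, data.frame(
          x_um = (ci - 0.5) * pixel_size, y_um = (ri - 0.5) * pixel_size,
          area_px = NA_integer_, score = resp[i, j], peak = frame[i, j]))
      }
    }
  }
  feats
}

#' Detect intracellular spot features in a cell-centered stack
#'
#' Finds stable bright blobs in every frame of a cell-centered sub-movie.
#' The default detector is a maximally-stable-extremal-regions analysis: an
#' intensity threshold sweep in which each bright core is followed through
#' the nested component tree and reported at the threshold where its area
#' is most stable (relative area variation below `max_variation`). A
#' Laplacian-of-Gaussian blob detector is available behind the same
#' contract. Centroids are refined with a background-subtracted
#' intensity-weighted mean over the detected region (sub-pixel).
#'
#' Coordinates are reported in the cell frame: micrometers relative to the
#' crop center, with the crop's sub-pixel residual (if present) added back.
#'
#' @param cell_stack A `cell_stack` from [crop_cell_frame()], or a plain
#'   3D array (then `pixel_size` must be given).
#' @param method `"mser"` (default) or `"log"`.
#' @param pixel_size um per pixel (taken from the `cell_stack` if present).
#' @param n_levels Threshold levels in the MSER sweep.
#' @param max_variation Maximum relative area variation for a stable region.
#' @param min_area,max_area Area limits in pixels.
#' @param min_contrast Minimum peak height above the frame median, in units
#'   of the frame MAD.
#' @param sigma_um LoG scale (um), `"log"` method only.
#' @return data.frame with `frame`, `x_cm`, `y_cm` (um, cell frame),
#'   `area_px`, `score`, `peak`. Frames with no stable feature contribute
#'   no rows.
#' @export
detect_spot_features <- function(cell_stack, method = c("mser", "log"),
                                 pixel_size = NULL, n_levels = 24L,
                                 max_variation = 0.35, min_area = 3L,
                                 max_area = 120L, min_contrast = 6,
                                 sigma_um = 0.6) {
  method <- match.arg(method)
  if (inherits(cell_stack, "cell_stack")) {
    stack <- cell_stack$stack
    pixel_size <- cell_stack$pixel_size
    residual <- cell_stack$residual_um
    frames_ids <- cell_stack$track$frame
    half_px <- cell_stack$half_px
  } else {
    stack <- cell_stack
    if (is.null(pixel_size)) stop("pixel_size required for a plain array")
    residual <- NULL
    frames_ids <- seq_len(dim(stack)[3])
    half_px <- (dim(stack)[1] - 1L) / 2
  }
  center_um <- (half_px + 0.5) * pixel_size
  out <- NULL
  for (f in seq_len(dim(stack)[3])) {
    frame <- stack[, , f]
    feats <- switch(method,
      mser = detect_mser_frame(frame, pixel_size, n_levels, max_variation,
                               min_area, max_area, min_contrast),
      log = detect_log_frame(frame, pixel_size, sigma_um, min_contrast))
    if (is.null(feats) || nrow(feats) == 0L) next
    # crop center -> cell frame; remove the sub-pixel crop residual (the
    # crop is centered on the rounded centroid, residual = centroid - center)
    feats$x_cm <- feats$x_um - center_um
    feats$y_cm <- feats$y_um - center_um
    if (!is.null(residual)) {
      feats$x_cm <- feats$x_cm - residual$dx_um[f]
      feats$y_cm <- feats$y_cm - residual$dy_um[f]
    }
    feats$frame <- frames_ids[f]
    out <- rbind(out, feats[c("frame", "x_cm", "y_cm", "area_px", "score", "peak")])
  }
  if (is.null(out)) {
    out <- data.frame(frame = integer(0), x_cm = numeric(0), y_cm = numeric(0),
                      area_px = integer(0), score = numeric(0), peak = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Link spot features into per-spot trajectories
#'
#' Nearest-neighbour linking in the cell frame with gap tolerance; spots
#' with distinct transverse (y) positions are kept apart by the gate.
#' Trajectories shorter than `min_length` are discarded.
#'
#' @param features data.frame from [detect_spot_features()].
#' @param gate_um Maximum frame-to-frame displacement in um.
#' @param gap_frames Frames a trajectory may go undetected (default 3).
#' @param min_length Minimum trajectory length in frames.
#' @param y_weight Transverse displacements are inflated by this factor in
#'   the linking distance: a spot's y stays constant during on-axis
#'   rolling, so y jumps signal a different spot (default 3).
#' @return List of `spot_trajectory` data.frames (`frame`, `x_cm`, `y_cm`).
#' @export
link_spot_trajectory <- function(features, gate_um = 2, gap_frames = 3L,
                                 min_length = 10L, y_weight = 3) {
  if (nrow(features) == 0L) return(list())
  det <- data.frame(frame = features$frame, x_um = features$x_cm,
                    y_um = features$y_cm)
  tracks <- greedy_link(det, gate_um, gap_frames, min_length,
                        y_weight = y_weight)
  lapply(tracks, function(tr) {
    out <- data.frame(frame = tr$frame, x_cm = tr$x_um, y_cm = tr$y_um)
    class(out) <- c("spot_trajectory", "data.frame")
    out
  })
}
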