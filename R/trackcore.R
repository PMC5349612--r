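# Whole-cell translational tracking: segmentation, linking, velocity, crops.

#' Segment cells in a single frame
#'
#' Binary threshold (Otsu by default) followed by connected-component
#' labelling; components smaller than `min_area_px` are discarded.
#' Centroids are the binary-mask centroids, reported in micrometers
#' (x = flow direction = image columns).
#'
#' @param frame Numeric matrix (one movie frame).
#' @param pixel_size um per pixel.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold_value Intensity threshold when `threshold_method =
#'   "fixed"` (on the raw intensity scale).
#' @param min_area_px Minimum component area in pixels.
#' @return data.frame with one row per region: `label`, `x_um`, `y_um`,
#'   `area_px`, ordered by `x_um`. Zero rows if the frame is empty.
#' @export
segment_cells <- function(frame, pixel_size,
                          threshold_method = c("otsu", "fixed"),
                          threshold_value = NULL, min_area_px = 50) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(is.matrix(frame), pixel_size > 0)
  rng <- range(frame)
  if (rng[1] == rng[2]) {
    return(data.frame(label = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_px = integer(0)))
  }
  if (threshold_method == "otsu") {
    # clip the brightest pixels (intracellular scatterers) so the histogram
    # stays bimodal background-vs-cell and Otsu does not jump to the spots
    capped <- pmin(frame, stats::quantile(frame, 0.98))
    rng <- range(capped)
    norm <- (capped - rng[1]) / (rng[2] - rng[1])
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- norm > thr
  } else {
    if (is.null(threshold_value)) stop("threshold_value required for fixed threshold")
    mask <- frame > threshold_value
  }
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  nlab <- max(labm)
  if (nlab == 0) {
    return(data.frame(label = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_px = integer(0)))
  }
  # EBImage images are column-major with dim (x, y) relative to display;
  # our matrices are (row = y, col = x), which bwlabel treats symmetrically.
  idx <- which(labm > 0)
  lb <- labm[idx]
  ri <- (idx - 1) %% nrow(frame) + 1
  ci <- (idx - 1) %/% nrow(frame) + 1
  area <- as.vector(table(factor(lb, levels = seq_len(nlab))))
  cx <- as.vector(tapply(ci, lb, mean))
  cy <- as.vector(tapply(ri, lb, mean))
  keep <- which(area >= min_area_px)
  out <- data.frame(label = keep,
                    x_um = (cx[keep] - 0.5) * pixel_size,
                    y_um = (cy[keep] - 0.5) * pixel_size,
                    area_px = area[keep])
  out[order(out$x_um), , drop = FALSE]
}

#' Segment every frame of a movie
#'
#' @param movie 3D array ny x nx x nframes.
#' @inheritParams segment_cells
#' @return data.frame with columns `frame`, `x_um`, `y_um`, `area_px`.
#' @export
segment_movie <- function(movie, pixel_size, threshold_method = "otsu",
                          threshold_value = NULL, min_area_px = 50) {
  stopifnot(length(dim(movie)) == 3L)
  res <- lapply(seq_len(dim(movie)[3]), function(f) {
    d <- segment_cells(movie[, , f], pixel_size, threshold_method,
                       threshold_value, min_area_px)
    if (nrow(d) > 0) d$frame <- f
    d
  })
  out <- do.call(rbind, res[vapply(res, nrow, 1L) > 0])
  if (is.null(out)) {
    return(data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_px = integer(0)))
  }
  out[c("frame", "x_um", "y_um", "area_px")]
}

# greedy nearest-neighbour association used for both cell and spot linking
greedy_link <- function(detections, max_jump, gap_frames = 0L,
                        min_length = 2L, frame_interval = NULL,
                        y_weight = 1) {
  if (nrow(detections) == 0L) return(list())
  detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(detections$frame))
  tracks <- list()        # finished
  active <- list()        # each: data.frame rows + last frame/pos
  for (f in frames) {
    det <- detections[detections$frame == f, , drop = FALSE]
    used <- rep(FALSE, nrow(det))
    if (length(active) > 0L) {
      # candidate pairs within gate; greedy by distance, ties by smaller y
      cand <- NULL
      for (a in seq_along(active)) {
        last <- active[[a]]$last
        if (f - last$frame > gap_frames + 1L) next
        d <- sqrt((det$x_um - last$x_um)^2 + (y_weight * (det$y_um - last$y_um))^2)
        ok <- which(d <= max_jump * (f - last$frame))
        if (length(ok) > 0L) {
          cand <- rbind(cand, data.frame(a = a, j = ok, d = d[ok],
                                         y = det$y_um[ok]))
        }
      }
      if (!is.null(cand)) {
        cand <- cand[order(cand$d, cand$y), , drop = FALSE]
        taken_a <- logical(length(active))
        for (k in seq_len(nrow(cand))) {
          a <- cand$a[k]; j <- cand$j[k]
          if (taken_a[a] || used[j]) next
          taken_a[a] <- TRUE; used[j] <- TRUE
          active[[a]]$rows <- rbind(active[[a]]$rows, det[j, , drop = FALSE])
          active[[a]]$last <- det[j, , drop = FALSE]
        }
      }
    }
    # retire stale tracks
    if (length(active) > 0L) {
      stale <- vapply(active, function(tr) f - tr$last$frame > gap_frames,
                      logical(1))
      tracks <- c(tracks, lapply(active[stale], `[[`, "rows"))
      active <- active[!stale]
    }
    # new tracks from unused detections
    for (j in which(!used)) {
      active <- c(active, list(list(rows = det[j, , drop = FALSE],
                                    last = det[j, , drop = FALSE])))
    }
  }
  tracks <- c(tracks, lapply(active, `[[`, "rows"))
  tracks <- Filter(function(tr) nrow(tr) >= min_length, tracks)
  lapply(tracks, function(tr) {
    rownames(tr) <- NULL
    if (!is.null(frame_interval)) tr$t <- (tr$frame - 1L) * frame_interval
    tr
  })
}

#' Link per-frame cell centroids into tracks
#'
#' Greedy nearest-neighbour association frame to frame. A detection is used
#' by at most one track; a track ends when no detection falls within the
#' gate for more than `gap_frames` consecutive frames. Equidistant
#' candidates are broken deterministically toward the smaller y coordinate.
#'
#' @param detections data.frame from [segment_movie()] (`frame`, `x_um`,
#'   `y_um`, ...).
#' @param max_jump_um Linking gate: maximum displacement per frame in um
#'   (typically one cell radius).
#' @param gap_frames Frames a track may go undetected before termination.
#' @param min_length Minimum track length to keep.
#' @param frame_interval If given, a `t` column (seconds) is added.
#' @return List of `cell_track` data.frames.
#' @export
link_cell_tracks <- function(detections, max_jump_um, gap_frames = 2L,
                             min_length = 2L, frame_interval = NULL) {
  stopifnot(max_jump_um > 0)
  tracks <- greedy_link(detections, max_jump_um, gap_frames, min_length,
                        frame_interval)
  lapply(tracks, function(tr) { class(tr) <- c("cell_track", "data.frame"); tr })
}

#' Instantaneous cell velocity along the flow axis
#'
#' Central-difference velocity of the x (flow) coordinate with optional
#' moving-average smoothing; the endpoints use one-sided differences.
#'
#' @param track A `cell_track` (needs `t` and `x_um`).
#' @param smoothing_window Odd moving-average window (1 = none).
#' @return Numeric vector v(t) in um/s, same length as the track.
#' @export
cell_velocity <- function(track, smoothing_window = 1L) {
  stopifnot(nrow(track) >= 2L, !is.null(track$t))
  x <- track$x_um; t <- track$t; n <- length(x)
  v <- numeric(n)
  if (n == 2L) {
    v[] <- (x[2] - x[1]) / (t[2] - t[1])
  } else {
    v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
    v[1] <- (x[2] - x[1]) / (t[2] - t[1])
    v[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  }
  moving_average(v, smoothing_window)
}

#' Cell-centered sub-movie
#'
#' Crops a square box around the tracked centroid in every frame using
#' integer-pixel shifts; the sub-pixel residual of each shift is recorded
#' so downstream coordinates can be corrected without interpolating (and
#' smoothing) the spot images. Frames at the movie edge are padded with the
#' background value and flagged.
#'
#' @param movie 3D array ny x nx x nframes.
#' @param track A `cell_track` covering the frames to crop.
#' @param box_half_width_um Half-width of the crop box in um (>= cell
#'   radius).
#' @param pixel_size um per pixel.
#' @param background Padding value (default: the movie intensity minimum).
#' @return List of class `cell_stack`: `stack` (array), `residual_um`
#'   (data.frame `frame`, `dx_um`, `dy_um`: centroid minus crop center),
#'   `padded` (logical per frame), `pixel_size`, `track`.
#' @export
crop_cell_frame <- function(movie, track, box_half_width_um, pixel_size,
                            background = NULL) {
  stopifnot(length(dim(movie)) == 3L)
  ny <- dim(movie)[1]; nx <- dim(movie)[2]
  half_px <- as.integer(round(box_half_width_um / pixel_size))
  size <- 2L * half_px + 1L
  background <- background %||% min(movie)
  n <- nrow(track)
  ccol <- as.integer(round(track$x_um / pixel_size + 0.5))
  crow <- as.integer(round(track$y_um / pixel_size + 0.5))
  if (any(ccol < 1L | ccol > nx | crow < 1L | crow > ny)) {
    stop("track centroid lies outside the movie")
  }
  stack <- array(background, dim = c(size, size, n))
  padded <- logical(n)
  for (i in seq_len(n)) {
    r0 <- crow[i] - half_px; r1 <- crow[i] + half_px
    c0 <- ccol[i] - half_px; c1 <- ccol[i] + half_px
    rr <- max(r0, 1L):min(r1, ny)
    cc <- max(c0, 1L):min(c1, nx)
    padded[i] <- (r0 < 1L || r1 > ny || c0 < 1L || c1 > nx)
    stack[rr - r0 + 1L, cc - c0 + 1L, i] <- movie[rr, cc, track$frame[i]]
  }
  residual <- data.frame(
    frame = track$frame,
    dx_um = track$x_um - (ccol - 0.5) * pixel_size,
    dy_um = track$y_um - (crow - 0.5) * pixel_size
  )
  structure(list(stack = stack, residual_um = residual, padded = padded,
                 pixel_size = pixel_size, half_px = half_px, track = track),
            class = "cell_stack")
}

#' Export a cell track as CSV
#'
#' Columns: frame, t, x_um, y_um, v_um_s.
#'
#' @param track A `cell_track`.
#' @param path Output path.
#' @param smoothing_window Passed to [cell_velocity()].
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path, smoothing_window = 1L) {
  df <- data.frame(frame = track$frame, t = track$t,
                   x_um = track$x_um, y_um = track$y_um,
                   v_um_s = cell_velocity(track, smoothing_window))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
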