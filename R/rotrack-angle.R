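# Rotation reconstruction from spot trajectories: radial distance, arccos
# angle unfolding, cumulative angle, angular velocity, traction labels,
# circumference from the theta-vs-x slope.

#' Estimate a spot's radial distance from its x-trace
#'
#' As the cell rolls, a spot's cell-frame x coordinate follows
#' \eqn{R\cos(\theta + \phi)}; the extreme excursion of the trace is the
#' radial distance R of the spot in the rolling plane. The default
#' estimator is the maximal |x| (exact for noise-free data but biased high
#' under noise); the robust alternatives are the 99th-percentile excursion
#' and the amplitude of a cosine fit.
#'
#' @param traj A `spot_trajectory` (or data.frame with `x_cm`).
#' @param estimator `"max"`, `"percentile"`, or `"cosfit"`.
#' @param probs Quantile used by the percentile estimator.
#' @param min_amplitude_um Traces whose excursion never exceeds this are
#'   rejected (spot on the rotation axis).
#' @return R in micrometers, with attribute `estimator`.
#' @export
estimate_radial_distance <- function(traj, estimator = c("max", "percentile",
                                                         "cosfit"),
                                     probs = 0.99, min_amplitude_um = 0.5) {
  estimator <- match.arg(estimator)
  x <- traj$x_cm
  x <- x[is.finite(x)]
  if (length(x) < 8L) stop("trajectory too short to estimate R")
  # coverage: the trace must span a full oscillation (both extremes visited)
  xs <- moving_average(x, min(5L, length(x)))
  n <- length(xs)
  interior_max <- any(local_maxima(xs) > 1)
  interior_min <- any(local_maxima(-xs) > 1)
  if (max(abs(x)) < min_amplitude_um) {
    stop("x_cm excursion (", signif(max(abs(x)), 3),
         " um) too small: spot lies on the rotation axis")
  }
  if (!(interior_max && interior_min)) {
    stop("trajectory does not span a full oscillation of x_cm ",
         "(interior max: ", interior_max, ", interior min: ", interior_min,
         "); track more cycles")
  }
  R <- switch(estimator,
    max = max(abs(x)),
    # light smoothing before the quantile: the extreme excursions of a
    # noisy trace overshoot R, and the quantile of the raw |x| inherits
    # most of that bias
    percentile = as.numeric(stats::quantile(abs(moving_average(x, 5L)),
                                            probs)),
    cosfit = {
      t0 <- seq_along(x)
      # frequency seed from the dominant FFT component
      sp <- Mod(stats::fft(x - mean(x)))[2:floor(n / 2)]
      f0 <- which.max(sp) / n
      fit <- try(stats::nls(x ~ A * cos(2 * pi * f * t0 + p) + c0,
                            start = list(A = diff(range(x)) / 2, f = f0,
                                         p = 0, c0 = mean(x)),
                            control = stats::nls.control(warnOnly = TRUE)),
                 silent = TRUE)
      if (inherits(fit, "try-error")) max(abs(x))
      else abs(stats::coef(fit)[["A"]])
    })
  attr(R, "estimator") <- estimator
  R
}

#' Reconstruct the relative rotation angle from a spot x-trace
#'
#' The raw angle \eqn{\alpha = \cos^{-1}(x_{cm}/R) \in [0, \pi]} is
#' degenerate: a rolling cell passes each \eqn{\alpha} twice per cycle. The
#' degeneracy is removed by flipping alternating intervals about \eqn{\pi}
#' (\eqn{\theta' = 2\pi - \alpha}) so each cycle progresses monotonically
#' from 0 to \eqn{2\pi}. Interval boundaries are the turning points where
#' the trace visits \eqn{\alpha \approx 0} or \eqn{\pi}; because arccos
#' amplifies noise there, a turning point is committed only after the raw
#' angle has retreated from its running extremum by more than `hysteresis`
#' radians (alternating-extremum extraction), which also tolerates a biased
#' R estimate that keeps alpha short of 0 or pi. The global flip parity is
#' set by the sign convention that the cell rolls along +x (cumulative
#' theta increasing); a reverse-rolling trace would be unfolded with the
#' opposite parity automatically.
#'
#' @param traj A `spot_trajectory`.
#' @param R Radial distance in um (> 0), e.g. from
#'   [estimate_radial_distance()].
#' @param hysteresis Retreat (rad) from a running extremum required to
#'   commit a turning point (default 0.6; true turnings reverse by ~pi,
#'   noise excursions stay well below).
#' @param clamp_tolerance Samples with |x|/R in (1, 1 + tol\] are clamped and
#'   flagged; beyond that they are dropped as likely mislinks.
#' @return data.frame with `frame`, `theta_rel` in \[0, 2pi), `alpha` (raw
#'   arccos), `clamped`, `dropped`; attribute `n_flips`.
#' @export
reconstruct_angle <- function(traj, R, hysteresis = 0.6,
                              clamp_tolerance = 0.1) {
  if (!is.numeric(R) || R <= 0) stop("R must be > 0")
  x <- traj$x_cm
  ratio <- x / R
  dropped <- abs(ratio) > 1 + clamp_tolerance
  clamped <- abs(ratio) > 1 & !dropped
  alpha <- acos(clamp(ratio, -1, 1))
  keep <- !dropped
  a <- alpha[keep]
  n <- length(a)
  if (n < 3L) stop("too few usable samples after dropping out-of-range ones")

  # turning points by alternating-extremum extraction: a candidate extremum
  # of alpha is committed only once the trace has retreated from it by more
  # than the hysteresis threshold. Because the rotation is monotone, true
  # turnings reverse alpha by ~pi while noise excursions stay far below the
  # threshold; this is also insensitive to a biased R, which merely keeps
  # alpha short of 0 or pi.
  flips <- integer(0)
  cand_hi <- 1L; cand_lo <- 1L; dir <- 0L
  for (i in seq_len(n)[-1]) {
    if (a[i] > a[cand_hi]) cand_hi <- i
    if (a[i] < a[cand_lo]) cand_lo <- i
    if (dir >= 0L && a[cand_hi] - a[i] > hysteresis && a[cand_hi] >= pi / 2) {
      flips <- c(flips, cand_hi)
      dir <- -1L; cand_lo <- i
    } else if (dir <= 0L && a[i] - a[cand_lo] > hysteresis &&
               a[cand_lo] <= pi / 2) {
      flips <- c(flips, cand_lo)
      dir <- 1L; cand_hi <- i
    }
  }
  # refine each flip to the sub-sample crossing: alpha is locally a tent
  # around the true turning, so if its interpolated apex falls before the
  # extremal sample, that sample already belongs to the next interval
  if (length(flips) > 0L) {
    for (k in seq_along(flips)) {
      f <- flips[k]
      if (f <= 1L || f >= n) next
      curv <- 2 * a[f] - a[f - 1L] - a[f + 1L]
      if (abs(curv) < 1e-12) next
      delta <- (a[f + 1L] - a[f - 1L]) / (2 * curv)
      if (delta < 0) flips[k] <- f - 1L
    }
    # an endpoint can be committed when the trace starts or ends mid-ascent;
    # it partitions nothing (and at a genuine boundary turning the branches
    # are wrap-equivalent), so drop it
    flips <- sort(unique(flips))
    flips <- flips[flips > 1L & flips < n]
  }
  # alternate branches between turning points; fix global parity by the
  # sign convention that cumulative theta increases along the flow
  seg <- findInterval(seq_len(n), flips + 1L) %% 2L
  unfold <- function(parity) {
    b <- (seg + parity) %% 2L
    wrap_2pi(ifelse(b == 0L, a, 2 * pi - a))
  }
  trend <- function(rel) {
    cum <- accumulate_angle(rel)
    stats::cov(seq_len(n), cum) / stats::var(seq_len(n))
  }
  t0 <- unfold(0L)
  theta_rel_keep <- if (trend(t0) >= 0) t0 else unfold(1L)
  theta_rel <- rep(NA_real_, length(x))
  theta_rel[keep] <- wrap_2pi(theta_rel_keep)
  out <- data.frame(frame = traj$frame, theta_rel = theta_rel, alpha = alpha,
                    clamped = clamped, dropped = dropped)
  attr(out, "n_flips") <- length(flips)
  out
}

#' Accumulate a relative angle into a cumulative rotation angle
#'
#' Adds a 2-pi offset every time the relative angle wraps (a negative jump
#' larger than pi between consecutive samples).
#'
#' @param theta_rel Relative angle samples in \[0, 2pi) (NA allowed at
#'   trace gaps; carried through).
#' @return Cumulative angle in radians, same length.
#' @export
accumulate_angle <- function(theta_rel) {
  n <- length(theta_rel)
  if (n == 0L) return(numeric(0))
  idx <- which(is.finite(theta_rel))
  if (length(idx) == 0L) return(theta_rel)
  v <- theta_rel[idx]
  d <- diff(v)
  wraps <- cumsum(c(0, ifelse(d < -pi, 2 * pi, ifelse(d > pi, -2 * pi, 0))))
  out <- rep(NA_real_, n)
  out[idx] <- v + wraps
  out
}

circular_mean <- function(x) atan2(mean(sin(x)), mean(cos(x)))

wrap_pi <- function(x) (x + pi) %% (2 * pi) - pi

#' Merge relative-angle traces from multiple feature points
#'
#' Feature points of the same (or different) spots measure the same cell
#' rotation up to a constant phase offset. Offsets against a reference
#' trace (the longest) are estimated as circular means of the pairwise
#' differences; after offset removal the traces are combined by a per-frame
#' circular mean. Traces whose residual circular deviation from the
#' reference exceeds `max_residual` are excluded and reported.
#'
#' @param angle_traces List of data.frames (`frame`, `theta_rel`).
#' @param max_residual Exclusion threshold in radians (default pi/4).
#' @return data.frame `frame`, `theta_rel` (merged, phase of the reference
#'   trace), `sd` (per-frame circular SD), `n_traces`; attribute `excluded`
#'   (indices of dropped traces), attribute `offsets`.
#' @export
merge_feature_angles <- function(angle_traces, max_residual = pi / 4) {
  stopifnot(length(angle_traces) >= 1L)
  traces <- lapply(angle_traces, function(tr)
    tr[is.finite(tr$theta_rel), c("frame", "theta_rel")])
  lens <- vapply(traces, nrow, 1L)
  ref <- traces[[which.max(lens)]]
  offsets <- numeric(length(traces))
  resid <- numeric(length(traces))
  for (j in seq_along(traces)) {
    m <- merge(ref, traces[[j]], by = "frame", suffixes = c("_ref", "_j"))
    if (nrow(m) < 2L) { resid[j] <- Inf; next }
    dphi <- m$theta_rel_j - m$theta_rel_ref
    offsets[j] <- circular_mean(dphi)
    resid[j] <- mean(abs(wrap_pi(dphi - offsets[j])))
  }
  excluded <- which(resid > max_residual)
  use <- setdiff(seq_along(traces), excluded)
  if (length(use) == 0L) stop("no traces could be phase-aligned")
  frames <- sort(unique(unlist(lapply(traces[use], `[[`, "frame"))))
  sin_s <- matrix(NA_real_, length(frames), length(use))
  cos_s <- matrix(NA_real_, length(frames), length(use))
  wgt <- matrix(NA_real_, length(frames), length(use))
  for (k in seq_along(use)) {
    tr <- traces[[use[k]]]
    al <- tr$theta_rel - offsets[use[k]]
    i <- match(tr$frame, frames)
    sin_s[i, k] <- sin(al); cos_s[i, k] <- cos(al)
    # arccos error variance scales as 1/sin^2: inverse-variance weights
    wgt[i, k] <- sin(tr$theta_rel)^2 + 0.02
  }
  ns <- rowSums(!is.na(sin_s))
  wsum <- rowSums(wgt, na.rm = TRUE)
  ms <- rowSums(sin_s * wgt, na.rm = TRUE) / wsum
  mc <- rowSums(cos_s * wgt, na.rm = TRUE) / wsum
  merged <- wrap_2pi(atan2(ms, mc))
  # unweighted resultant as the quality metric
  ms0 <- rowMeans(sin_s, na.rm = TRUE); mc0 <- rowMeans(cos_s, na.rm = TRUE)
  Rbar <- pmin(sqrt(ms0^2 + mc0^2), 1)
  circ_sd <- sqrt(pmax(-2 * log(Rbar), 0))
  out <- data.frame(frame = frames, theta_rel = merged, sd = circ_sd,
                    n_traces = ns)
  attr(out, "excluded") <- excluded
  attr(out, "offsets") <- offsets
  out
}

#' Angular velocity from a cumulative angle trace
#'
#' Central difference of the cumulative angle over time with optional
#' moving-average smoothing (endpoints one-sided), as in [cell_velocity()].
#'
#' @param theta_cum Cumulative angle (rad).
#' @param t Sample times (s), same length.
#' @param smoothing_window Odd moving-average window (1 = none).
#' @return omega(t) in rad/s.
#' @export
angular_velocity <- function(theta_cum, t, smoothing_window = 1L) {
  stopifnot(length(theta_cum) == length(t), length(t) >= 2L)
  n <- length(t)
  om <- numeric(n)
  if (n == 2L) {
    om[] <- (theta_cum[2] - theta_cum[1]) / (t[2] - t[1])
  } else {
    om[2:(n - 1)] <- (theta_cum[3:n] - theta_cum[1:(n - 2)]) /
      (t[3:n] - t[1:(n - 2)])
    om[1] <- (theta_cum[2] - theta_cum[1]) / (t[2] - t[1])
    om[n] <- (theta_cum[n] - theta_cum[n - 1]) / (t[n] - t[n - 1])
  }
  moving_average(om, smoothing_window)
}

#' Traction classification from the rotation-per-distance metric
#'
#' Computes the dimensionless metric \eqn{r\,d\theta/dx} over sliding
#' windows: about 1 while the cell maintains traction (pure rolling,
#' v = r omega) and at or below 0.5 while the cell is transiently detached
#' and convected by the flow. Windows whose x-range is degenerate (stalled
#' cell) are labelled ambiguous rather than divided by zero.
#'
#' @param theta_cum Cumulative angle (rad).
#' @param x Cell position along flow (um), same frames.
#' @param r Cell radius (um).
#' @param window Sliding window length in samples (odd).
#' @param rolling_min Metric at or above this labels `rolling` (default
#'   0.75).
#' @param detached_max Metric at or below this labels `detached` (default
#'   0.5).
#' @param min_dx_um Minimum window x-range for a defined slope.
#' @return data.frame `metric` (r dtheta/dx) and `label` in
#'   `c("rolling", "detached", "ambiguous")`, one row per sample.
#' @export
traction_classification <- function(theta_cum, x, r, window = 9L,
                                    rolling_min = 0.75, detached_max = 0.5,
                                    min_dx_um = 0.2) {
  stopifnot(length(theta_cum) == length(x))
  n <- length(x)
  if (window %% 2L == 0L) window <- window + 1L
  half <- min((window - 1L) %/% 2L, n - 1L)
  metric <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    xs <- x[lo:hi]; th <- theta_cum[lo:hi]
    ok <- is.finite(xs) & is.finite(th)
    if (sum(ok) < 2L) next
    xs <- xs[ok]; th <- th[ok]
    if (diff(range(xs)) < min_dx_um) next
    sl <- stats::cov(xs, th) / stats::var(xs)
    metric[i] <- r * sl
  }
  label <- rep("ambiguous", n)
  label[!is.na(metric) & metric >= rolling_min] <- "rolling"
  label[!is.na(metric) & metric <= detached_max] <- "detached"
  data.frame(metric = metric, label = label)
}

#' Cell diameter from the slope of cumulative angle versus position
#'
#' During traction, \eqn{\theta = x / r}, so the least-squares slope s of
#' cumulative angle against position over rolling-labelled samples gives
#' the radius r = 1/s and diameter d = 2/s, independent of imaging
#' calibration of the apparent cell outline. Detached samples are excluded;
#' at least `min_cycles` full rotations of rolling data are required.
#'
#' @param theta_cum Cumulative angle (rad).
#' @param x Position (um).
#' @param label Traction labels from [traction_classification()] (or NULL
#'   to use all samples).
#' @param min_cycles Minimum rolling rotation span (default 4).
#' @return Diameter d in um, with attributes `slope` (rad/um) and
#'   `n_cycles`.
#' @export
circumference_from_slope <- function(theta_cum, x, label = NULL,
                                     min_cycles = 4) {
  keep <- is.finite(theta_cum) & is.finite(x)
  if (!is.null(label)) keep <- keep & label == "rolling"
  if (sum(keep) < 4L) stop("too few rolling samples")
  cycles <- diff(range(theta_cum[keep])) / (2 * pi)
  if (cycles < min_cycles) {
    stop("only ", signif(cycles, 3), " rolling cycles available; ",
         min_cycles, " required")
  }
  # each detachment shifts x ahead of theta; fit within contiguous rolling
  # segments (per-segment centering) so intercept jumps cannot tilt the slope
  runs <- rle(keep)
  seg_id <- rep(seq_along(runs$lengths), runs$lengths)
  th <- theta_cum[keep]; xs <- x[keep]; seg <- seg_id[keep]
  th <- th - stats::ave(th, seg)
  xs <- xs - stats::ave(xs, seg)
  s <- sum(xs * th) / sum(xs^2)
  d <- 2 / s
  attr(d, "slope") <- s
  attr(d, "n_cycles") <- cycles
  d
}
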