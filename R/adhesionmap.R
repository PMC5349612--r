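# Dwell-time adhesion maps and periodicity analysis.

#' Dwell time per unit angle
#'
#' The adhesion proxy \eqn{\tau(\theta) = 1/\omega(\theta)}: the time the
#' cell spends per radian of rotation at contact angle theta. Only
#' rolling-labelled samples are used; samples whose angular velocity falls
#' below the floor (stalls, which would produce unbounded tau) are excluded
#' and counted.
#'
#' @param theta_cum Cumulative angle (rad).
#' @param omega Angular velocity (rad/s), same frames.
#' @param label Optional traction labels; only `"rolling"` samples are kept.
#' @param omega_floor_frac Floor as a fraction of the median rolling omega
#'   (default 0.01).
#' @return data.frame `theta`, `tau` (s/rad); attribute `n_excluded`.
#' @export
dwell_time <- function(theta_cum, omega, label = NULL,
                       omega_floor_frac = 0.01) {
  stopifnot(length(theta_cum) == length(omega))
  keep <- is.finite(theta_cum) & is.finite(omega)
  if (!is.null(label)) keep <- keep & label == "rolling"
  med <- stats::median(omega[keep & omega > 0])
  if (!is.finite(med) || med <= 0) stop("no usable rolling samples with omega > 0")
  floor_om <- omega_floor_frac * med
  below <- keep & omega < floor_om
  keep <- keep & omega >= floor_om
  if (!any(keep)) stop("all samples fall below the angular-velocity floor")
  out <- data.frame(theta = theta_cum[keep], tau = 1 / omega[keep])
  attr(out, "n_excluded") <- sum(below)
  out
}

#' Resample dwell samples onto a uniform angular grid
#'
#' Linear interpolation of tau over cumulative theta onto a grid of spacing
#' `delta`, aligned to absolute multiples of `delta` so bin phases are
#' comparable across cells. Grid points farther than `gap_max` from the
#' nearest sample (e.g. inside a detachment interval, where no rolling
#' dwell exists) are set to NA rather than interpolated across the gap;
#' downstream autocorrelation handles them pairwise.
#'
#' @param theta Cumulative angle samples (rad), increasing.
#' @param tau Dwell samples (s/rad).
#' @param delta Grid spacing (rad), default 2pi/100.
#' @param gap_max Maximum distance (rad) to the nearest sample for a grid
#'   point to be interpolated (default `3 * delta`); `Inf` interpolates
#'   across all gaps.
#' @return data.frame `theta`, `tau` on the uniform grid (NA in gaps).
#' @export
resample_dwell <- function(theta, tau, delta = 2 * pi / 100,
                           gap_max = 3 * delta) {
  ord <- order(theta)
  theta <- theta[ord]; tau <- tau[ord]
  g0 <- ceiling(min(theta) / delta) * delta
  g1 <- floor(max(theta) / delta) * delta
  if (g1 <= g0) stop("trace too short to resample")
  grid <- seq(g0, g1, by = delta)
  out <- stats::approx(theta, tau, xout = grid, ties = "ordered")$y
  if (is.finite(gap_max)) {
    prev <- stats::approx(theta, theta, xout = grid, method = "constant",
                          f = 0, ties = "ordered")$y
    nxt <- stats::approx(theta, theta, xout = grid, method = "constant",
                         f = 1, ties = "ordered")$y
    gap <- nxt - prev    # width of the sample interval bracketing each point
    out[!is.na(gap) & gap > gap_max] <- NA_real_
  }
  data.frame(theta = grid, tau = out)
}

#' Stack dwell time over 2-pi rotation periods
#'
#' Resamples tau onto a uniform angular grid, folds the grid by full
#' rotation cycles, and reports the per-bin mean and standard deviation of
#' the dwell across cycles -- the single-cell adhesion map. Only cycles
#' fully covered by data are stacked.
#'
#' @param theta Cumulative angle samples (rad).
#' @param tau Dwell samples (s/rad).
#' @param n_bins Angular bins per 2-pi period (default 100).
#' @param min_coverage Fraction of bins a cycle must cover (after gap
#'   masking) to be stacked.
#' @return Object of class `dwell_map`: `bin_centers`, `bin_edges` (rad in
#'   \[0, 2pi)), `tau_cycles` (cycles x bins matrix), `mean`, `sd`,
#'   `n_cycles`, `n_per_bin`.
#' @export
stack_dwell_periods <- function(theta, tau, n_bins = 100L,
                                min_coverage = 0.9) {
  delta <- 2 * pi / n_bins
  rs <- resample_dwell(theta, tau, delta)
  bin_idx <- round(rs$theta / delta) %% n_bins       # absolute phase bin
  cycle <- floor(round(rs$theta / delta) / n_bins)
  cycles <- sort(unique(cycle))
  # keep cycles with (near-)complete coverage; detachment gaps are NA
  full <- cycles[vapply(cycles, function(k)
    sum(cycle == k & is.finite(rs$tau)) >= min_coverage * n_bins,
    logical(1))]
  if (length(full) < 2L) {
    stop("need at least 2 complete rotation cycles; found ", length(full))
  }
  m <- matrix(NA_real_, length(full), n_bins)
  for (i in seq_along(full)) {
    sel <- cycle == full[i]
    m[i, bin_idx[sel] + 1L] <- rs$tau[sel]
  }
  n_per_bin <- colSums(is.finite(m))
  structure(list(
    bin_centers = (seq_len(n_bins) - 1L) * delta,
    bin_edges = seq(0, 2 * pi, length.out = n_bins + 1L) - delta / 2,
    tau_cycles = m,
    mean = colMeans(m, na.rm = TRUE),
    sd = apply(m, 2, stats::sd, na.rm = TRUE),
    n_cycles = nrow(m),
    n_per_bin = n_per_bin
  ), class = "dwell_map")
}

#' @export
print.dwell_map <- function(x, ...) {
  cat("<dwell_map>", length(x$bin_centers), "bins x", x$n_cycles,
      "cycles; mean tau", signif(mean(x$mean), 3), "s/rad\n")
  invisible(x)
}

# shared builder for periodicity results
periodicity_result <- function(lag, acf_vals, period_nominal, units,
                               window_frac = 0.1, min_height = 0) {
  delta <- lag[2] - lag[1]
  max_lag <- lag[length(lag)]
  peaks <- NULL
  n_max <- floor(max_lag / period_nominal + 0.25)
  if (n_max >= 1) {
    for (k in seq_len(n_max)) {
      center <- k * period_nominal
      win <- which(abs(lag - center) <= window_frac * period_nominal)
      win <- win[win > 1 & win < length(lag) & is.finite(acf_vals[win])]
      if (length(win) == 0L) next
      i <- win[which.max(acf_vals[win])]
      is_local <- isTRUE(acf_vals[i] > acf_vals[i - 1]) &&
        isTRUE(acf_vals[i] >= acf_vals[i + 1])
      if (is_local && acf_vals[i] > min_height) {
        peaks <- rbind(peaks, data.frame(order = k, lag = lag[i],
                                         value = acf_vals[i]))
      }
    }
  }
  period <- NA_real_
  if (!is.null(peaks)) {
    period <- if (nrow(peaks) >= 2L) stats::median(diff(peaks$lag) /
                                                   diff(peaks$order))
              else peaks$lag[1] / peaks$order[1]
  }
  structure(list(lag = lag, acf = acf_vals, peaks = peaks, period = period,
                 period_nominal = period_nominal, units = units,
                 delta = delta),
            class = "periodicity_result")
}

#' @export
print.periodicity_result <- function(x, ...) {
  cat("<periodicity_result>", length(x$lag), "lags (", x$units, "), period",
      signif(x$period, 4), "\n")
  if (!is.null(x$peaks)) print(x$peaks)
  invisible(x)
}

#' Autocorrelation of the dwell time over cumulative angle
#'
#' Mean-subtracted, biased-normalized autocorrelation (lag 0 = 1) of tau
#' sampled on a uniform cumulative-theta grid. Peaks are local maxima
#' within windows of half-width 0.2 pi centered on the candidate lags
#' \eqn{2 n \pi}; a repeating adhesion pattern shows up as peaks at every
#' full rotation.
#'
#' @param tau Dwell samples on a uniform theta grid (e.g. from
#'   [resample_dwell()]).
#' @param delta Grid spacing in rad.
#' @param theta Optional grid (used only to verify uniform spacing).
#' @param max_lag Maximum lag in rad (default 4 full rotations).
#' @param min_periods Minimum data span in periods (default 4).
#' @param min_height Minimum autocorrelation value for a reported peak.
#' @return A `periodicity_result` with lags in rad.
#' @export
dwell_autocorrelation <- function(tau, delta = 2 * pi / 100, theta = NULL,
                                  max_lag = 8 * pi, min_periods = 4,
                                  min_height = 0) {
  if (!is.null(theta)) {
    d <- diff(theta)
    if (max(abs(d - d[1])) > 1e-6 * abs(d[1])) {
      stop("theta grid is not uniform; resample first (see resample_dwell)")
    }
    delta <- d[1]
  }
  fin <- which(is.finite(tau))
  if (length(fin) < 2L) stop("no finite dwell samples")
  tau <- tau[seq(fin[1], fin[length(fin)])]   # trim NA edges, keep gaps
  span <- (length(tau) - 1L) * delta
  if (span < min_periods * 2 * pi) {
    stop("trace spans ", signif(span / (2 * pi), 3), " periods; ",
         min_periods, " required")
  }
  nlag <- min(floor(max_lag / delta), length(tau) - 1L)
  rho <- acf_biased(tau, nlag)
  periodicity_result(lag = (0:nlag) * delta, acf_vals = rho,
                     period_nominal = 2 * pi, units = "rad",
                     window_frac = 0.1, min_height = min_height)
}

#' Average autocorrelation functions over a population
#'
#' Mean of per-cell autocorrelation functions on their common lag grid
#' (truncated to the shortest); only peaks shared across the population sum
#' constructively.
#'
#' @param results List of `periodicity_result`s with identical lag spacing
#'   and units.
#' @return A `periodicity_result` for the population average.
#' @export
average_autocorrelations <- function(results) {
  stopifnot(length(results) >= 1L)
  deltas <- vapply(results, `[[`, numeric(1), "delta")
  if (max(abs(deltas - deltas[1])) > 1e-9) {
    stop("autocorrelations must share one lag grid")
  }
  units <- results[[1]]$units
  n <- min(vapply(results, function(r) length(r$lag), 1L))
  m <- vapply(results, function(r) r$acf[seq_len(n)], numeric(n))
  periodicity_result(lag = results[[1]]$lag[seq_len(n)],
                     acf_vals = rowMeans(m, na.rm = TRUE),
                     period_nominal = results[[1]]$period_nominal,
                     units = units)
}

#' Characteristic patch size from the autocorrelation peak width
#'
#' Measures the full width at half maximum of the zero-lag peak (first
#' crossings of 0.5) and converts it to a fraction of the circumference by
#' calibrating against a periodic top-hat patch, whose mean-subtracted
#' autocorrelation has FWHM \eqn{= w(1 - w/P)} for patch width w and period
#' P: the reported fraction is \eqn{(1 - \sqrt{1 - 4\,\mathrm{FWHM}/P})/2},
#' which returns exactly w/P for top-hat patches and reduces to FWHM/P for
#' narrow peaks.
#'
#' @param result A `periodicity_result`.
#' @return Patch size as a fraction of the circumference. If the
#'   autocorrelation never falls below 0.5 within the first period the
#'   fraction is reported as 0.5 with attribute `flagged = TRUE`.
#' @export
patch_size_fraction <- function(result) {
  stopifnot(inherits(result, "periodicity_result"))
  P <- result$period_nominal
  lag <- result$lag; rho <- result$acf
  in_first <- which(lag <= P)
  below <- which(rho[in_first] < 0.5)
  if (length(below) == 0L) {
    out <- 0.5
    attr(out, "flagged") <- TRUE
    return(out)
  }
  i <- below[1]
  # linear interpolation of the 0.5 crossing
  x0 <- lag[i - 1]; x1 <- lag[i]; y0 <- rho[i - 1]; y1 <- rho[i]
  half_width <- x0 + (0.5 - y0) * (x1 - x0) / (y1 - y0)
  fw <- 2 * half_width / P
  frac <- if (fw >= 0.25) 0.5 else (1 - sqrt(1 - 4 * fw)) / 2
  attr(frac, "flagged") <- fw >= 0.25
  attr(frac, "fwhm") <- 2 * half_width
  frac
}

#' Positional (translation-only) dwell autocorrelation
#'
#' The control analysis: dwell per radian inferred from translation alone,
#' \eqn{\tau_x(x) = \hat r / v(x)} with a fixed assumed radius, sampled
#' uniformly in x including detachment spans. The same autocorrelation
#' estimator is applied on the x axis; the population average is reported
#' on a lag grid in micrometers with candidate peaks at multiples of
#' \eqn{\pi \langle d \rangle}.
#'
#' @param traces List of data.frames with columns `x` (um) and `tau`.
#' @param mean_diameter Population mean diameter (um), sets the candidate
#'   period pi*<d>.
#' @param delta_x Resampling step in um.
#' @param max_lag_um Maximum lag in um.
#' @return List with `per_cell` (list of `periodicity_result`) and
#'   `average` (`periodicity_result`).
#' @export
positional_dwell_autocorrelation <- function(traces, mean_diameter,
                                             delta_x = 0.5,
                                             max_lag_um = NULL) {
  if (length(traces) == 0L) stop("empty population")
  period <- pi * mean_diameter
  max_lag_um <- max_lag_um %||% (4 * period)
  per_cell <- lapply(traces, function(tr) {
    ord <- order(tr$x)
    xs <- tr$x[ord]; ta <- tr$tau[ord]
    g0 <- ceiling(min(xs) / delta_x) * delta_x
    g1 <- floor(max(xs) / delta_x) * delta_x
    grid <- seq(g0, g1, by = delta_x)
    tg <- stats::approx(xs, ta, xout = grid, ties = "ordered")$y
    nlag <- min(floor(max_lag_um / delta_x), length(tg) - 1L)
    rho <- acf_biased(tg, nlag)
    periodicity_result((0:nlag) * delta_x, rho, period_nominal = period,
                       units = "um")
  })
  list(per_cell = per_cell, average = average_autocorrelations(per_cell))
}

#' Polar adhesion map figure and CSV export
#'
#' Renders the stacked dwell map as a polar plot: log-scale radial line
#' with an SD band, plus a linear color ring along the circumference. The
#' numeric map (angle, mean, SD) can be exported as CSV with
#' [write_dwell_csv()].
#'
#' @param dwell_map A `dwell_map`.
#' @param path Optional PNG path; if given the figure is written there.
#' @return The ggplot object, invisibly.
#' @export
polar_map <- function(dwell_map, path = NULL) {
  stopifnot(inherits(dwell_map, "dwell_map"))
  df <- data.frame(angle = dwell_map$bin_centers,
                   tau = dwell_map$mean,
                   lo = pmax(dwell_map$mean - dwell_map$sd,
                             min(dwell_map$mean) * 0.5),
                   hi = dwell_map$mean + dwell_map$sd)
  ring <- df
  ring$tau_ring <- max(df$hi) * 1.15
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data$tau)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_point(data = ring,
                        ggplot2::aes(y = .data$tau_ring, color = .data$tau),
                        size = 2, show.legend = TRUE) +
    ggplot2::scale_color_gradient(low = "blue", high = "red",
                                  name = "mean tau (s/rad)") +
    ggplot2::scale_y_log10() +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::scale_x_continuous(limits = c(0, 2 * pi),
                                breaks = seq(0, 3 * pi / 2, pi / 2),
                                labels = c("0", "pi/2", "pi", "3pi/2")) +
    ggplot2::labs(x = NULL, y = "dwell time (s/rad, log)") +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 5, height = 5, dpi = 150)
  }
  invisible(p)
}

#' @rdname polar_map
#' @param path_csv CSV output path.
#' @export
write_dwell_csv <- function(dwell_map, path_csv) {
  df <- data.frame(angle_rad = dwell_map$bin_centers,
                   tau_mean = dwell_map$mean,
                   tau_sd = dwell_map$sd,
                   n_cycles = dwell_map$n_cycles)
  utils::write.csv(df, path_csv, row.names = FALSE)
  invisible(path_csv)
}
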