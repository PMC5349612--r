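# Small numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Moving-average smoothing with one-sided ends
#'
#' Centered moving average of odd window length; samples near the ends are
#' averaged over the available (shorter, one-sided) window so the output has
#' the same length as the input and no NA padding.
#'
#' @param x Numeric vector.
#' @param window Odd integer window length (1 = no smoothing).
#' @return Numeric vector of `length(x)`.
#' @keywords internal
moving_average <- function(x, window) {
  stopifnot(is.numeric(x))
  if (window <= 1L) return(x)
  if (window > length(x)) {
    stop("smoothing window (", window, ") is longer than the series (",
         length(x), ")")
  }
  if (window %% 2L == 0L) window <- window + 1L
  half <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Indices of strict local maxima of a vector
#'
#' @param x Numeric vector.
#' @param min_value Discard maxima below this value.
#' @return Integer indices (interior points only).
#' @keywords internal
local_maxima <- function(x, min_value = -Inf) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  i[x[i] >= min_value]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# wrap angle into [0, 2*pi)
wrap_2pi <- function(theta) theta %% (2 * pi)

#' Mean-subtracted, normalized autocorrelation
#'
#' The estimator used throughout the periodicity analysis:
#' \eqn{\rho_k = \hat c_k / \hat c_0} with
#' \eqn{\hat c_k = \sum_i (x_i - \bar x)(x_{i+k} - \bar x) / N_k},
#' where \eqn{N_k} counts the pairs available at lag k. Per-lag
#' normalization keeps a strictly periodic signal's peaks near 1 at every
#' multiple of its period; NA samples (gaps, e.g. detachment intervals)
#' are handled pairwise by excluding them from the products and counts.
#' Long-lag variance is controlled by capping `max_lag` well below the
#' series length rather than by 1/N shrinkage.
#'
#' @param x Numeric vector; NAs mark gaps.
#' @param max_lag Maximum lag in samples.
#' @return Numeric vector of length `max_lag + 1` (lags 0..max_lag).
#' @keywords internal
acf_biased <- function(x, max_lag) {
  x <- as.numeric(x)
  n <- length(x)
  stopifnot(n >= 2L, max_lag >= 0L)
  max_lag <- min(max_lag, n - 1L)
  ok <- is.finite(x)
  if (sum(ok) < 2L) stop("fewer than 2 finite samples")
  xc <- x - mean(x[ok])
  if (sum(xc[ok]^2) <= 0) stop("series has zero variance; autocorrelation undefined")
  xz <- ifelse(ok, xc, 0)
  m <- 2^ceiling(log2(2L * n))
  f <- stats::fft(c(xz, rep(0, m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(max_lag + 1L)] / m
  if (all(ok)) {
    cnt <- n - (0:max_lag)
  } else {
    okz <- as.numeric(ok)
    fo <- stats::fft(c(okz, rep(0, m - n)))
    cnt <- Re(stats::fft(fo * Conj(fo), inverse = TRUE))[seq_len(max_lag + 1L)] / m
    cnt <- pmax(round(cnt), 0)
  }
  cov_k <- ifelse(cnt > 0, ac / cnt, NA_real_)
  cov_k / cov_k[1]
}

# Running rectangular sums of a matrix over kh x kw windows (valid positions),
# computed with cumulative sums. Used by the normalized cross-correlation.
window_sums <- function(mat, kh, kw) {
  cs <- t(apply(apply(mat, 2, cumsum), 1, cumsum)) # 2D cumulative sum table
  cs <- rbind(0, cbind(0, cs))
  nh <- nrow(mat) - kh + 1L
  nw <- ncol(mat) - kw + 1L
  cs[(kh + 1L):(kh + nh), (kw + 1L):(kw + nw), drop = FALSE] -
    cs[(kh + 1L):(kh + nh), 1:nw, drop = FALSE] -
    cs[1:nh, (kw + 1L):(kw + nw), drop = FALSE] +
    cs[1:nh, 1:nw, drop = FALSE]
}

# 2D cross-correlation of image with kernel at all "valid" offsets, via FFT.
# Returns matrix of size (nrow(img)-nrow(ker)+1) x (ncol(img)-ncol(ker)+1)
# where element [i, j] = sum(img[i:(i+kh-1), j:(j+kw-1)] * ker).
xcorr2_valid <- function(img, ker) {
  ih <- nrow(img); iw <- ncol(img)
  kh <- nrow(ker); kw <- ncol(ker)
  stopifnot(kh <= ih, kw <= iw)
  mh <- 2^ceiling(log2(ih + kh)); mw <- 2^ceiling(log2(iw + kw))
  pad <- function(m, h, w) {
    out <- matrix(0, h, w)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  fi <- stats::fft(pad(img, mh, mw))
  # correlation = convolution with flipped kernel
  fk <- stats::fft(pad(ker[kh:1, kw:1, drop = FALSE], mh, mw))
  full <- Re(stats::fft(fi * fk, inverse = TRUE)) / (mh * mw)
  full[kh:ih, kw:iw, drop = FALSE]
}

#' Zero-normalized 2D cross-correlation (ZNCC)
#'
#' Correlation of `template` against every valid placement in `image`, with
#' both the template and each image window mean-subtracted and scaled to unit
#' norm, so values lie in \[-1, 1\] and a perfect match scores 1.
#'
#' @param image Numeric matrix (search image).
#' @param template Numeric matrix, no larger than `image` in either dimension.
#' @return Matrix of correlation scores at valid offsets.
#' @keywords internal
zncc <- function(image, template) {
  kh <- nrow(template); kw <- ncol(template)
  npix <- kh * kw
  t0 <- template - mean(template)
  tnorm <- sqrt(sum(t0^2))
  if (tnorm == 0) stop("template has zero variance")
  num <- xcorr2_valid(image, t0)
  s1 <- window_sums(image, kh, kw)
  s2 <- window_sums(image^2, kh, kw)
  var_w <- s2 - s1^2 / npix
  var_w[var_w < 0] <- 0
  den <- sqrt(var_w) * tnorm
  out <- num / den
  out[den <= .Machine$double.eps^0.5] <- 0
  clamp(out, -1, 1)
}
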