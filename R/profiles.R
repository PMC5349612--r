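#' Construct a patchy angular adhesion profile
#'
#' The ground-truth dwell-time profile \eqn{\tau(\theta)} used by all
#' simulators: a constant baseline dwell (seconds per radian of rotation)
#' plus additive top-hat "adhesion patches". Inside a patch of multiplier
#' \eqn{m} the dwell is \eqn{\tau = \tau_0 (1 + m)}; overlapping patches
#' combine additively. The profile is 2\eqn{\pi}-periodic by construction.
#'
#' Dwell time per unit angle is the reciprocal of the angular velocity,
#' so a region of high dwell is a region where the rolling cell lingers --
#' the simulator's notion of a strongly adhesive patch on the contact
#' circumference.
#'
#' @param patches `data.frame` with columns `center` (rad), `width` (rad, in
#'   (0, 2pi)) and `multiplier` (>= 1), one row per patch; or `NULL` for a
#'   flat profile.
#' @param baseline_dwell Baseline dwell in s/rad; must be > 0.
#' @return An object of class `adhesion_profile`: a list with the inputs and
#'   a vectorized evaluator available through [profile_dwell()].
#' @examples
#' prof <- adhesion_profile(data.frame(center = pi, width = pi / 2,
#'                                     multiplier = 9), baseline_dwell = 0.1)
#' profile_dwell(prof, c(0, pi)) # 0.1, 1.0
#' @export
adhesion_profile <- function(patches = NULL, baseline_dwell = 0.1) {
  if (!is.numeric(baseline_dwell) || length(baseline_dwell) != 1L ||
      !is.finite(baseline_dwell) || baseline_dwell <= 0) {
    stop("baseline_dwell must be a single positive number (s/rad), got: ",
         deparse(baseline_dwell))
  }
  if (is.null(patches) || NROW(patches) == 0L) {
    patches <- data.frame(center = numeric(0), width = numeric(0),
                          multiplier = numeric(0))
  }
  patches <- as.data.frame(patches)
  req <- c("center", "width", "multiplier")
  if (!all(req %in% names(patches))) {
    stop("patches must have columns center, width, multiplier")
  }
  if (any(patches$width <= 0 | patches$width >= 2 * pi)) {
    stop("patch width must lie in (0, 2*pi)")
  }
  if (any(patches$multiplier < 1)) {
    stop("patch multiplier must be >= 1")
  }
  patches$center <- wrap_2pi(patches$center)
  structure(list(baseline_dwell = baseline_dwell,
                 patches = patches[req],
                 period = 2 * pi),
            class = "adhesion_profile")
}

#' Evaluate a dwell-time profile
#'
#' @param profile An [adhesion_profile()].
#' @param theta Angles in radians (any real values; evaluated mod 2pi).
#' @return Dwell time tau(theta) in s/rad, same length as `theta`.
#' @export
profile_dwell <- function(profile, theta) {
  stopifnot(inherits(profile, "adhesion_profile"))
  th <- wrap_2pi(theta)
  mult <- rep(0, length(th))
  p <- profile$patches
  if (nrow(p) > 0L) {
    for (i in seq_len(nrow(p))) {
      # circular distance to patch center
      d <- abs(wrap_2pi(th - p$center[i] + pi) - pi)
      mult <- mult + p$multiplier[i] * (d <= p$width[i] / 2)
    }
  }
  profile$baseline_dwell * (1 + mult)
}

#' @export
print.adhesion_profile <- function(x, ...) {
  cat("<adhesion_profile> baseline", x$baseline_dwell, "s/rad,",
      nrow(x$patches), "patch(es)\n")
  if (nrow(x$patches) > 0L) print(x$patches)
  invisible(x)
}

#' Mean angular velocity implied by a profile
#'
#' One full rotation takes \eqn{\int_0^{2\pi} \tau(\theta) d\theta} seconds;
#' the cycle-average angular velocity is \eqn{2\pi} over that time.
#'
#' @param profile An [adhesion_profile()].
#' @param n Quadrature points per period.
#' @return Mean omega in rad/s.
#' @export
profile_mean_omega <- function(profile, n = 4096L) {
  th <- (seq_len(n) - 0.5) * 2 * pi / n
  2 * pi / (sum(profile_dwell(profile, th)) * 2 * pi / n)
}

#' Read / write adhesion profiles as YAML
#'
#' @param profile An [adhesion_profile()].
#' @param path File path.
#' @return `write_profile_yaml` returns `path` invisibly;
#'   `read_profile_yaml` returns an [adhesion_profile()].
#' @export
write_profile_yaml <- function(profile, path) {
  stopifnot(inherits(profile, "adhesion_profile"))
  yaml::write_yaml(list(
    baseline_dwell = profile$baseline_dwell,
    patches = if (nrow(profile$patches) > 0L)
      lapply(seq_len(nrow(profile$patches)), function(i)
        as.list(profile$patches[i, ])) else list()
  ), path, precision = 12L)
  invisible(path)
}

#' @rdname write_profile_yaml
#' @export
read_profile_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  patches <- if (length(spec$patches) > 0L)
    do.call(rbind, lapply(spec$patches, as.data.frame)) else NULL
  adhesion_profile(patches, baseline_dwell = spec$baseline_dwell)
}
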