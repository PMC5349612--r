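#' Flow-channel description
#'
#' Geometry and operating point of a thin parallel-plate flow chamber of the
#' kind used for rolling-adhesion assays (height much smaller than width).
#'
#' @param h0 Channel height in micrometers.
#' @param w0 Channel width in micrometers.
#' @param mu Dynamic viscosity in Pa s (default water at room temperature,
#'   1.0e-3 Pa s).
#' @param Q Volumetric flow rate in microliters per hour.
#' @return An object of class `flow_channel`.
#' @examples
#' ch <- flow_channel(h0 = 80, w0 = 2000, Q = 100)
#' wall_shear_stress(ch) # ~0.013 Pa
#' @export
flow_channel <- function(h0, w0, mu = 1.0e-3, Q) {
  vals <- c(h0 = h0, w0 = w0, mu = mu, Q = Q)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad) > 0 && !identical(bad, "Q")) {
    stop("flow_channel fields must be positive and finite: ",
         paste(bad, collapse = ", "))
  }
  if (!is.finite(Q) || Q < 0) stop("Q must be finite and >= 0")
  if (h0 > w0) stop("h0 must not exceed w0 (thin-channel geometry)")
  structure(list(h0 = h0, w0 = w0, mu = mu, Q = Q), class = "flow_channel")
}

#' Wall shear stress in a parallel-plate flow chamber
#'
#' Infinite-parallel-plate law \eqn{\tau_w = 6 \mu Q / (w_0 h_0^2)}, the
#' standard approximation for thin rectangular channels with large
#' width-to-height aspect ratio (for an 80 um x 2 mm channel the aspect
#' ratio is 25:1 and the finite-width correction is a few percent).
#' Unit conversions (uL/hr to m^3/s, um to m) are handled internally.
#'
#' @param channel A [flow_channel()].
#' @return Wall shear stress in pascals.
#' @export
wall_shear_stress <- function(channel) {
  stopifnot(inherits(channel, "flow_channel"))
  Q_m3s <- channel$Q * 1e-9 / 3600      # uL/hr -> m^3/s
  h_m <- channel$h0 * 1e-6
  w_m <- channel$w0 * 1e-6
  6 * channel$mu * Q_m3s / (w_m * h_m^2)
}
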