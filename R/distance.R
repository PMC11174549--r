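#' Select the per-step angular displacement
#'
#' Between TO and IC the integrator accumulates positive and negative
#' angular-displacement buckets separately. The step displacement is whichever
#' has the larger magnitude, sign preserved: a dominant negative displacement
#' is how backward steps are recognised.
#'
#' @param theta_pos Accumulated positive displacement, rad (>= 0).
#' @param theta_neg Accumulated negative displacement, rad (<= 0).
#' @return Signed displacement, rad.
#' @export
#' @examples
#' select_displacement(0.8, -0.1) # 0.8
#' select_displacement(0.1, -0.9) # -0.9, a backward step
select_displacement <- function(theta_pos, theta_neg) {
  if (any(theta_pos < 0)) stop("theta_pos must be >= 0")
  if (any(theta_neg > 0)) stop("theta_neg must be <= 0")
  ifelse(theta_pos >= -theta_neg, theta_pos, theta_neg)
}

#' Chord-model step distance
#'
#' The step length is the chord of a circle of radius `L` (leg length)
#' subtended by the net shank angular displacement:
#' `d = L * sqrt(2 * (1 - cos(theta))) = 2 * L * sin(|theta|/2)`.
#' The sign of `theta` is discarded (backward steps cover positive ground);
#' magnitudes above pi are clamped with a warning, since beyond pi the chord
#' is no longer monotone and no single step sweeps further.
#'
#' The `2 L sin(theta/2)` form is used numerically: it is exact, even in
#' `theta`, and stable for small angles.
#'
#' @param theta Signed angular displacement, rad (vectorised).
#' @param leg_length Leg length `L`, metres (> 0).
#' @return Distance in metres, in `[0, 2 * leg_length]`.
#' @export
#' @examples
#' step_distance(pi / 3, 1.0) # exactly 1
step_distance <- function(theta, leg_length) {
  if (!is.numeric(leg_length) || any(leg_length <= 0)) {
    stop("leg_length must be > 0")
  }
  a <- abs(theta)
  if (any(a > pi)) {
    warning("|theta| > pi clamped to pi", call. = FALSE)
    a <- pmin(a, pi)
  }
  2 * leg_length * sin(a / 2)
}
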