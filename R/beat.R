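#' Cilium beat model
#'
#' Loads the coefficient table of the planar parametric beat cycle and
#' returns an evaluable beat model. The centerline is defined by its tangent
#' angle `psi(s, phi)` (from the wall normal toward the effective-stroke
#' direction x'), expressed as a truncated Fourier series in the beat phase
#' `phi` (cycles) with polynomial dependence on the arclength fraction `s`:
#' `psi = sum_m s^m * sum_n [a_mn cos(2 pi n phi) + b_mn sin(2 pi n phi)]`.
#' Integrating the unit tangent yields the centerline, so the arclength
#' equals the cilium length exactly at every phase, the base is anchored at
#' the origin, and the shape is exactly 1-periodic in phase.
#'
#' The bundled table (`beat_coefficients_synthetic.csv`) is a synthetic
#' parametric beat constructed to reproduce the qualitative kinematics of
#' tracheal cilia: a fast, nearly straight effective stroke occupying about
#' the first third of the cycle (reference states 1-4 of 13) and a slow
#' recovery stroke in which the cilium bends backward toward the epithelium
#' (states 5-13). It is not a digitization of any published experimental
#' beat; see the package vignette for the construction.
#'
#' @param coefficients path to a coefficient CSV with columns `m` (arclength
#'   power), `n` (harmonic), `a`, `b`, or a data.frame of the same shape;
#'   defaults to the bundled synthetic table.
#' @param length_um cilium length L (um).
#' @param frequency_hz beat frequency (Hz); the beat period is its inverse.
#' @param n_states number of reference states per cycle (13 by default).
#' @param n_quad quadrature panels used to integrate the tangent.
#' @return object of class `beat_model`.
#' @export
beat_model <- function(coefficients = NULL, length_um = 5, frequency_hz = 15,
                       n_states = 13, n_quad = 200) {
  if (is.null(coefficients)) {
    coefficients <- system.file("extdata", "beat_coefficients_synthetic.csv",
                                package = "mucosim", mustWork = TRUE)
  }
  tab <- if (is.character(coefficients)) {
    utils::read.csv(coefficients)
  } else {
    as.data.frame(coefficients)
  }
  if (!all(c("m", "n", "a", "b") %in% names(tab)) || nrow(tab) < 2) {
    stop("beat coefficient table must have columns m, n, a, b")
  }
  stopifnot(length_um > 0, frequency_hz > 0)
  structure(list(
    table = tab,
    L = um_to_m(length_um),
    f = frequency_hz,
    T_c = 1 / frequency_hz,
    n_states = n_states,
    n_quad = n_quad,
    # effective stroke: fast forward sweep, first ~4 of 13 states
    effective_window = c(0, 4 / n_states)
  ), class = "beat_model")
}

#' @export
print.beat_model <- function(x, ...) {
  cat(sprintf(
    "<beat_model> L=%.3g um, f=%g Hz, %d harmonics x s^0..%d, %d states\n",
    m_to_um(x$L), x$f, max(x$table$n), max(x$table$m), x$n_states))
  invisible(x)
}

# tangent angle psi(s, phi) and its phase derivative; s, phi vectors of
# equal length (or one scalar)
beat_psi <- function(model, s, phi, deriv = FALSE) {
  tab <- model$table
  out <- 0
  for (i in seq_len(nrow(tab))) {
    ang <- 2 * pi * tab$n[i] * phi
    base <- if (deriv) {
      2 * pi * tab$n[i] * (-tab$a[i] * sin(ang) + tab$b[i] * cos(ang))
    } else {
      tab$a[i] * cos(ang) + tab$b[i] * sin(ang)
    }
    out <- out + base * s^tab$m[i]
  }
  out
}

#' Cilium centerline position
#'
#' @param model a [beat_model()].
#' @param phase beat phase in cycles; any real (1-periodic).
#' @param s arclength fraction(s) in `[0, 1]`.
#' @return matrix `length(s) x 3` of centerline points (m) in the beat frame:
#'   x' along the effective stroke, y' = 0 (planar beat), z wall-normal. The
#'   base `s = 0` maps to the origin.
#' @export
beat_shape <- function(model, phase, s = 1) {
  stopifnot(inherits(model, "beat_model"), all(s >= 0), all(s <= 1))
  sq <- seq(0, 1, length.out = model$n_quad + 1)
  psi <- beat_psi(model, sq, phase)
  dx <- sin(psi); dz <- cos(psi)
  hs <- 1 / model$n_quad
  cumx <- c(0, cumsum((dx[-1] + dx[-length(dx)]) / 2 * hs))
  cumz <- c(0, cumsum((dz[-1] + dz[-length(dz)]) / 2 * hs))
  x <- stats::approx(sq, cumx, xout = s)$y * model$L
  z <- stats::approx(sq, cumz, xout = s)$y * model$L
  cbind(x = x, y = 0 * x, z = z)
}

#' Cilium centerline velocity
#'
#' Time derivative of [beat_shape()] at fixed arclength, computed from the
#' analytic phase derivative of the tangent-angle Fourier series (scaled by
#' the beat frequency), not by finite differences.
#'
#' @inheritParams beat_shape
#' @return matrix `length(s) x 3` of velocities (m/s).
#' @export
beat_velocity <- function(model, phase, s = 1) {
  stopifnot(inherits(model, "beat_model"))
  sq <- seq(0, 1, length.out = model$n_quad + 1)
  psi <- beat_psi(model, sq, phase)
  dpsi <- beat_psi(model, sq, phase, deriv = TRUE)
  dxd <- cos(psi) * dpsi; dzd <- -sin(psi) * dpsi
  hs <- 1 / model$n_quad
  cumx <- c(0, cumsum((dxd[-1] + dxd[-length(dxd)]) / 2 * hs))
  cumz <- c(0, cumsum((dzd[-1] + dzd[-length(dzd)]) / 2 * hs))
  vx <- stats::approx(sq, cumx, xout = s)$y * model$L * model$f
  vz <- stats::approx(sq, cumz, xout = s)$y * model$L * model$f
  cbind(x = vx, y = 0 * vx, z = vz)
}

#' Numerically integrated centerline arclength
#'
#' Diagnostic: quadrature of `|dX/ds|` along the reconstructed centerline.
#' By the tangent-angle construction this equals the cilium length up to
#' quadrature error at every phase.
#'
#' @inheritParams beat_shape
#' @return arclength (m).
#' @export
beat_arclength <- function(model, phase) {
  sq <- seq(0, 1, length.out = model$n_quad + 1)
  pts <- beat_shape(model, phase, sq)
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 3])^2)
  sum(seg)
}
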