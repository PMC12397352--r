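#' Five-mode Giesekus parameters for airway mucus
#'
#' Default coefficients are the five-mode fit to cultured human bronchial
#' epithelial mucus in the healthy state: relaxation times `lambda` (s),
#' modal elastic viscosities `eta_p` (Pa s) and mobility factors `alpha`.
#' `alpha = 0` reduces a mode to upper-convected Maxwell; `alpha = 0.5`
#' gives the strongest shear thinning.
#'
#' @param lambda relaxation times (s), one per mode.
#' @param eta_p elastic viscosity contributions (Pa s).
#' @param alpha mobility parameters in `[0, 1]`.
#' @return object of class `giesekus_params`.
#' @export
giesekus_params <- function(
    lambda = c(0.0089, 0.0821, 0.466, 3.129, 49.733),
    eta_p = c(0.0298, 0.062, 0.2493, 1.4215, 2.2034),
    alpha = c(0.2, 0.3, 0.5, 0.5, 0.5)) {
  stopifnot(length(lambda) == length(eta_p),
            length(lambda) == length(alpha),
            all(lambda > 0), all(eta_p > 0),
            all(alpha >= 0), all(alpha <= 1))
  structure(list(lambda = lambda, eta_p = eta_p, alpha = alpha,
                 n_modes = length(lambda)), class = "giesekus_params")
}

#' @export
print.giesekus_params <- function(x, ...) {
  cat(sprintf("<giesekus_params> %d modes\n", x$n_modes))
  print(data.frame(lambda_s = x$lambda, eta_p_Pa_s = x$eta_p,
                   alpha = x$alpha))
  invisible(x)
}

# Symmetric tensors are stored as lists of 6 arrays (xx, yy, zz, xy, xz, yz).
tensor_zero <- function(dims) {
  lapply(stats::setNames(vector("list", 6),
                         c("xx", "yy", "zz", "xy", "xz", "yz")),
         function(dummy) array(0, dim = dims))
}

# tau . tau for symmetric tau in 6-component storage
tensor_square_sym <- function(t) {
  list(
    xx = t$xx * t$xx + t$xy * t$xy + t$xz * t$xz,
    yy = t$xy * t$xy + t$yy * t$yy + t$yz * t$yz,
    zz = t$xz * t$xz + t$yz * t$yz + t$zz * t$zz,
    xy = t$xx * t$xy + t$xy * t$yy + t$xz * t$yz,
    xz = t$xx * t$xz + t$xy * t$yz + t$xz * t$zz,
    yz = t$xy * t$xz + t$yy * t$yz + t$yz * t$zz
  )
}

# L . tau + tau . L^T for L given as 9 arrays L[[i]][[j]] = du_i/dx_j and
# symmetric tau; result symmetric.
tensor_ucd_stretch <- function(L, t) {
  tt <- list(t$xx, t$xy, t$xz, t$xy, t$yy, t$yz, t$xz, t$yz, t$zz)
  dim(tt) <- c(3, 3)
  get <- function(i, j) tt[[i, j]]
  comp <- function(i, j) {
    s1 <- L[[i]][[1]] * get(1, j) + L[[i]][[2]] * get(2, j) +
      L[[i]][[3]] * get(3, j)
    s2 <- get(i, 1) * L[[j]][[1]] + get(i, 2) * L[[j]][[2]] +
      get(i, 3) * L[[j]][[3]]
    s1 + s2
  }
  list(xx = comp(1, 1), yy = comp(2, 2), zz = comp(3, 3),
       xy = comp(1, 2), xz = comp(1, 3), yz = comp(2, 3))
}

#' Explicit Giesekus stress update (single mode, homogeneous or field)
#'
#' Advances one modal stress tensor by an explicit Euler step of
#' `d tau/dt = L.tau + tau.L^T - adv + (2 eta_p D - tau - (alpha lambda /
#' eta_p) tau.tau) / lambda`, i.e. the Giesekus constitutive law written
#' with its upper-convected derivative expanded. `L[[i]][[j]]` holds
#' `du_i/dx_j`; the advection term `u . grad(tau)` is supplied by the field
#' solver (zero for homogeneous states).
#'
#' @param tau list of 6 component arrays (xx, yy, zz, xy, xz, yz).
#' @param L velocity-gradient as a 3-list of 3-lists of arrays (1/s).
#' @param dt time step (s).
#' @param lambda,eta_p,alpha modal parameters.
#' @param adv optional advection contribution `u . grad(tau)` in the same
#'   6-component layout.
#' @return updated 6-component stress.
#' @export
giesekus_mode_step <- function(tau, L, dt, lambda, eta_p, alpha, adv = NULL) {
  D <- list(
    xx = L[[1]][[1]], yy = L[[2]][[2]], zz = L[[3]][[3]],
    xy = (L[[1]][[2]] + L[[2]][[1]]) / 2,
    xz = (L[[1]][[3]] + L[[3]][[1]]) / 2,
    yz = (L[[2]][[3]] + L[[3]][[2]]) / 2
  )
  st <- tensor_ucd_stretch(L, tau)
  sq <- tensor_square_sym(tau)
  out <- tau
  for (k in names(out)) {
    rhs <- st[[k]] +
      (2 * eta_p * D[[k]] - tau[[k]] - (alpha * lambda / eta_p) * sq[[k]]) /
      lambda
    if (!is.null(adv)) rhs <- rhs - adv[[k]]
    out[[k]] <- tau[[k]] + dt * rhs
    if (any(!is.finite(out[[k]]))) {
      stop("Giesekus stress update diverged (dt = ", dt,
           "); reduce the time step")
    }
  }
  out
}

#' Steady simple-shear stress of a single Giesekus mode
#'
#' Time-marches a homogeneous mode under constant shear rate to steady
#' state. For `alpha = 0` (upper-convected Maxwell) the steady state is the
#' closed form `tau_xy = eta_p * gdot`, `tau_xx = 2 eta_p lambda gdot^2`;
#' for `alpha > 0` it solves the nonlinear modal balance by marching.
#'
#' @param gdot shear rate (1/s), flow `u = (gdot * z, 0, 0)`.
#' @param lambda,eta_p,alpha modal parameters.
#' @param tol relative change convergence tolerance.
#' @param dt_factor step as a fraction of `lambda`.
#' @return named vector with components `xx`, `zz`, `xz` (Pa).
#' @export
giesekus_steady_shear <- function(gdot, lambda, eta_p, alpha,
                                  tol = 1e-12, dt_factor = 0.05) {
  dims <- c(1, 1, 1)
  zero <- array(0, dims)
  L <- list(list(zero, zero, array(gdot, dims)),
            list(zero, zero, zero),
            list(zero, zero, zero))
  tau <- tensor_zero(dims)
  dt <- dt_factor * lambda / max(1, lambda * abs(gdot))
  for (it in seq_len(200000)) {
    nxt <- giesekus_mode_step(tau, L, dt, lambda, eta_p, alpha)
    delta <- max(abs(nxt$xx - tau$xx), abs(nxt$xz - tau$xz),
                 abs(nxt$zz - tau$zz))
    scale <- max(abs(nxt$xx), abs(nxt$xz), 1e-300)
    tau <- nxt
    if (delta / scale < tol * dt / lambda) break
  }
  c(xx = tau$xx[1], zz = tau$zz[1], xz = tau$xz[1])
}
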