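#' Newtonian fluid properties of the ASL
#'
#' Both layers share the density and Newtonian (solvent) viscosity of water;
#' the mucus layer adds its elastic stress on top through the Giesekus
#' modes.
#'
#' @param density_kg_m3 density (kg/m3).
#' @param viscosity_Pa_s Newtonian dynamic viscosity (Pa s).
#' @return object of class `fluid_props` with kinematic viscosity `nu`.
#' @export
fluid_props <- function(density_kg_m3 = 1000, viscosity_Pa_s = 0.001) {
  stopifnot(density_kg_m3 > 0, viscosity_Pa_s > 0)
  structure(list(rho = density_kg_m3, mu = viscosity_Pa_s,
                 nu = viscosity_Pa_s / density_kg_m3),
            class = "fluid_props")
}

#' Two-layer ASL flow state
#'
#' Allocates the staggered velocity/pressure/stress state on a grid:
#' `u`, `v` on x/y faces (`nx x ny x nz`), `w` on z faces
#' (`nx x ny x (nz+1)`, wall faces pinned to zero), cell-centred pressure
#' and per-mode symmetric Giesekus stress (identically zero below the
#' PCL-mucus interface and in the top boundary layer).
#'
#' @param grid a [grid_spec()].
#' @param fluid a [fluid_props()].
#' @param giesekus a [giesekus_params()], or `NULL` for a purely Newtonian
#'   two-layer film.
#' @return object of class `flow_state`.
#' @export
flow_state <- function(grid, fluid = fluid_props(),
                       giesekus = giesekus_params()) {
  dims <- c(grid$nx, grid$ny, grid$nz)
  tau <- NULL
  if (!is.null(giesekus)) {
    tau <- lapply(seq_len(giesekus$n_modes), function(a) tensor_zero(dims))
  }
  structure(list(
    grid = grid, fluid = fluid, giesekus = giesekus,
    u = array(0, dims), v = array(0, dims),
    w = array(0, c(grid$nx, grid$ny, grid$nz + 1)),
    p = array(0, dims),
    tau = tau,
    mucus_mask = grid_mucus_mask(grid),
    t = 0
  ), class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<flow_state> %dx%dx%d, t = %.4g s, max|u| = %.3g um/s, %s\n",
              g$nx, g$ny, g$nz, x$t,
              m_to_um(max(abs(x$u), abs(x$v), abs(x$w))),
              if (is.null(x$tau)) "Newtonian" else
                sprintf("%d Giesekus modes", length(x$tau))))
  invisible(x)
}

## ---- spectral-tridiagonal elliptic solvers -------------------------------

# 2D FFT over the periodic x', y' axes of a 3D array
fft_xy <- function(a, inverse = FALSE) {
  d <- dim(a)
  m <- stats::mvfft(matrix(a, d[1], d[2] * d[3]), inverse = inverse)
  a2 <- aperm(array(m, d), c(2, 1, 3))
  m2 <- stats::mvfft(matrix(a2, d[2], d[1] * d[3]), inverse = inverse)
  aperm(array(m2, c(d[2], d[1], d[3])), c(2, 1, 3))
}

# eigenvalues of -(d2/dx2 + d2/dy2) for the periodic second difference
lap_eigen_xy <- function(nx, ny, h) {
  lx <- (2 - 2 * cos(2 * pi * (seq_len(nx) - 1) / nx)) / h^2
  ly <- (2 - 2 * cos(2 * pi * (seq_len(ny) - 1) / ny)) / h^2
  outer(lx, ly, `+`)
}

# Thomas algorithm vectorized over modes: sub/sup scalars, diag (nm x nK),
# rhs (nm x nK) complex
tridiag_modes <- function(sub, diag_m, sup, rhs) {
  nK <- ncol(rhs)
  cp <- matrix(0 + 0i, nrow(rhs), nK)
  dp <- cp
  cp[, 1] <- sup / diag_m[, 1]
  dp[, 1] <- rhs[, 1] / diag_m[, 1]
  if (nK > 1) {
    for (k in 2:nK) {
      den <- diag_m[, k] - sub * cp[, k - 1]
      cp[, k] <- sup / den
      dp[, k] <- (rhs[, k] - sub * dp[, k - 1]) / den
    }
  }
  x <- dp
  if (nK > 1) for (k in (nK - 1):1) x[, k] <- dp[, k] - cp[, k] * x[, k + 1]
  x
}

# Poisson solve  lap(phi) = rhs  with periodic x', y' and homogeneous
# Neumann in z (cell-centred); the free constant is fixed by pinning the
# mean mode. Exact for the discrete 7-point Laplacian.
poisson_neumann <- function(rhs, h) {
  d <- dim(rhs); nx <- d[1]; ny <- d[2]; nz <- d[3]
  lam <- as.vector(lap_eigen_xy(nx, ny, h))
  R <- fft_xy(rhs)
  Rm <- matrix(R, nx * ny, nz)
  diag_m <- matrix(-2 / h^2, nx * ny, nz) - lam
  diag_m[, 1] <- diag_m[, 1] + 1 / h^2
  diag_m[, nz] <- diag_m[, nz] + 1 / h^2
  # pin the singular mean mode: phi(k=1) = 0
  diag_m[1, 1] <- 1
  Rm[1, 1] <- 0
  sup_row <- rep(1 / h^2, nx * ny)
  # mode 1, k=1 must not couple upward
  X <- tridiag_modes_varsup(1 / h^2, diag_m, sup_row1 = c(0, rep(1 / h^2, 0)),
                            sup = 1 / h^2, rhs = Rm, kill_first_sup = TRUE)
  phi <- array(X, d)
  Re(fft_xy(phi, inverse = TRUE)) / (nx * ny)
}

# Thomas with scalar sub/sup but optionally decoupling the pinned first
# mode's first row from the rest of its column
tridiag_modes_varsup <- function(sub, diag_m, sup_row1, sup, rhs,
                                 kill_first_sup = FALSE) {
  nK <- ncol(rhs)
  nm <- nrow(rhs)
  cp <- matrix(0 + 0i, nm, nK)
  dp <- cp
  sup1 <- rep(sup, nm)
  if (kill_first_sup) sup1[1] <- 0
  cp[, 1] <- sup1 / diag_m[, 1]
  dp[, 1] <- rhs[, 1] / diag_m[, 1]
  if (nK > 1) {
    sub_k <- rep(sub, nm)
    for (k in 2:nK) {
      s <- sub_k
      if (kill_first_sup && k == 2) s[1] <- 0  # pinned row feeds nothing up
      den <- diag_m[, k] - s * cp[, k - 1]
      cp[, k] <- sup / den
      dp[, k] <- (rhs[, k] - s * dp[, k - 1]) / den
    }
  }
  x <- dp
  if (nK > 1) for (k in (nK - 1):1) x[, k] <- dp[, k] - cp[, k] * x[, k + 1]
  x
}

# Helmholtz solve (I - a lap) x = rhs for cell-centred z fields.
# bottom: no-slip wall (ghost = 2*u_wall - u1; the u_wall part must already
# be in rhs), top: free slip (zero normal gradient).
helmholtz_center <- function(rhs, a, h) {
  d <- dim(rhs); nx <- d[1]; ny <- d[2]; nz <- d[3]
  lam <- as.vector(lap_eigen_xy(nx, ny, h))
  R <- fft_xy(rhs)
  Rm <- matrix(R, nx * ny, nz)
  diag_m <- matrix(1 + 2 * a / h^2, nx * ny, nz) + a * lam
  diag_m[, 1] <- diag_m[, 1] + a / h^2      # Dirichlet wall via mirror ghost
  diag_m[, nz] <- diag_m[, nz] - a / h^2    # Neumann top
  X <- tridiag_modes(-a / h^2, diag_m, -a / h^2, Rm)
  Re(fft_xy(array(X, d), inverse = TRUE)) / (nx * ny)
}

# Helmholtz solve for w on interior z faces (Dirichlet 0 at both walls).
# rhs has dim (nx, ny, nz+1); wall faces are returned as zero.
helmholtz_face <- function(rhs, a, h) {
  d <- dim(rhs); nx <- d[1]; ny <- d[2]; nzp <- d[3]
  ni <- nzp - 2
  if (ni < 1) return(array(0, d))
  lam <- as.vector(lap_eigen_xy(nx, ny, h))
  R <- fft_xy(rhs[, , 2:(nzp - 1), drop = FALSE])
  Rm <- matrix(R, nx * ny, ni)
  diag_m <- matrix(1 + 2 * a / h^2, nx * ny, ni) + a * lam
  X <- tridiag_modes(-a / h^2, diag_m, -a / h^2, Rm)
  out <- array(0, d)
  out[, , 2:(nzp - 1)] <- Re(fft_xy(array(X, c(nx, ny, ni)),
                                    inverse = TRUE)) / (nx * ny)
  out
}

## ---- staggered operators --------------------------------------------------

# attach z ghost layers to a cell-centred array.
# bottom: "no_slip" (ghost = 2*wall - a1), "free_slip" (ghost = a1),
#         "zero", "dirichlet0" (ghost = -a1)
# top:    "free_slip", "zero", "dirichlet0"
zpad_center <- function(a, bottom = "no_slip", top = "free_slip", wall = 0) {
  d <- dim(a); nz <- d[3]
  g <- array(0, c(d[1], d[2], nz + 2))
  g[, , 2:(nz + 1)] <- a
  g[, , 1] <- switch(bottom,
    no_slip = 2 * wall - a[, , 1],
    free_slip = a[, , 1],
    dirichlet0 = -a[, , 1],
    zero = 0)
  g[, , nz + 2] <- switch(top,
    free_slip = a[, , nz],
    dirichlet0 = -a[, , nz],
    zero = 0)
  g
}

# discrete divergence at cell centres
flow_divergence <- function(u, v, w, h) {
  nz <- dim(u)[3]
  (u - shift_p(u, 1, -1) + v - shift_p(v, 2, -1) +
     w[, , 2:(nz + 1), drop = FALSE] - w[, , 1:nz, drop = FALSE]) / h
}

# central advection terms for the three staggered components
advection_terms <- function(u, v, w, h, wall_u = 0, wall_v = 0) {
  nz <- dim(u)[3]
  d2 <- 2 * h
  # --- u component (x faces) ---
  ux <- (shift_p(u, 1, 1) - shift_p(u, 1, -1)) / d2
  uy <- (shift_p(u, 2, 1) - shift_p(u, 2, -1)) / d2
  ug <- zpad_center(u, "no_slip", "free_slip", wall_u)
  uz <- (ug[, , 3:(nz + 2), drop = FALSE] - ug[, , 1:nz, drop = FALSE]) / d2
  vf <- (v + shift_p(v, 1, 1) + shift_p(v, 2, -1) +
           shift_p(shift_p(v, 1, 1), 2, -1)) / 4
  wf <- (w[, , 1:nz, drop = FALSE] + w[, , 2:(nz + 1), drop = FALSE] +
           shift_p(w, 1, 1)[, , 1:nz, drop = FALSE] +
           shift_p(w, 1, 1)[, , 2:(nz + 1), drop = FALSE]) / 4
  adv_u <- u * ux + vf * uy + wf * uz
  # --- v component (y faces) ---
  vx <- (shift_p(v, 1, 1) - shift_p(v, 1, -1)) / d2
  vy <- (shift_p(v, 2, 1) - shift_p(v, 2, -1)) / d2
  vg <- zpad_center(v, "no_slip", "free_slip", wall_v)
  vz <- (vg[, , 3:(nz + 2), drop = FALSE] - vg[, , 1:nz, drop = FALSE]) / d2
  uf <- (u + shift_p(u, 2, 1) + shift_p(u, 1, -1) +
           shift_p(shift_p(u, 1, -1), 2, 1)) / 4
  wfv <- (w[, , 1:nz, drop = FALSE] + w[, , 2:(nz + 1), drop = FALSE] +
            shift_p(w, 2, 1)[, , 1:nz, drop = FALSE] +
            shift_p(w, 2, 1)[, , 2:(nz + 1), drop = FALSE]) / 4
  adv_v <- uf * vx + v * vy + wfv * vz
  # --- w component (z faces; wall faces remain zero) ---
  adv_w <- array(0, dim(w))
  if (nz >= 2) {
    ks <- 2:nz
    wx <- (shift_p(w, 1, 1) - shift_p(w, 1, -1)) / d2
    wy <- (shift_p(w, 2, 1) - shift_p(w, 2, -1)) / d2
    wz <- (w[, , ks + 1, drop = FALSE] - w[, , ks - 1, drop = FALSE]) / d2
    uc <- (u + shift_p(u, 1, -1)) / 2
    vc <- (v + shift_p(v, 2, -1)) / 2
    uw <- (uc[, , ks - 1, drop = FALSE] + uc[, , ks, drop = FALSE]) / 2
    vw <- (vc[, , ks - 1, drop = FALSE] + vc[, , ks, drop = FALSE]) / 2
    adv_w[, , ks] <- uw * wx[, , ks, drop = FALSE] +
      vw * wy[, , ks, drop = FALSE] + w[, , ks, drop = FALSE] * wz
  }
  list(u = adv_u, v = adv_v, w = adv_w)
}

# explicit Laplacian of a cell-centred z field (for the CN explicit half)
laplacian_center <- function(a, h, bottom = "no_slip", top = "free_slip",
                             wall = 0) {
  nz <- dim(a)[3]
  g <- zpad_center(a, bottom, top, wall)
  (shift_p(a, 1, 1) + shift_p(a, 1, -1) + shift_p(a, 2, 1) +
     shift_p(a, 2, -1) - 4 * a +
     g[, , 3:(nz + 2), drop = FALSE] + g[, , 1:nz, drop = FALSE] - 2 * a) / h^2
}

laplacian_face <- function(w, h) {
  d <- dim(w); nzp <- d[3]
  out <- array(0, d)
  if (nzp >= 3) {
    ks <- 2:(nzp - 1)
    out[, , ks] <- (shift_p(w, 1, 1)[, , ks, drop = FALSE] +
                      shift_p(w, 1, -1)[, , ks, drop = FALSE] +
                      shift_p(w, 2, 1)[, , ks, drop = FALSE] +
                      shift_p(w, 2, -1)[, , ks, drop = FALSE] -
                      4 * w[, , ks, drop = FALSE] +
                      w[, , ks + 1, drop = FALSE] +
                      w[, , ks - 1, drop = FALSE] -
                      2 * w[, , ks, drop = FALSE]) / h^2
  }
  out
}

# velocity-gradient tensor at cell centres: L[[i]][[j]] = du_i/dx_j
velocity_gradient <- function(u, v, w, h, wall_u = 0, wall_v = 0) {
  nz <- dim(u)[3]
  d2 <- 2 * h
  uc <- (u + shift_p(u, 1, -1)) / 2
  vc <- (v + shift_p(v, 2, -1)) / 2
  wc <- (w[, , 1:nz, drop = FALSE] + w[, , 2:(nz + 1), drop = FALSE]) / 2
  dudx <- (u - shift_p(u, 1, -1)) / h
  dvdy <- (v - shift_p(v, 2, -1)) / h
  dwdz <- (w[, , 2:(nz + 1), drop = FALSE] - w[, , 1:nz, drop = FALSE]) / h
  grad_c <- function(a, bottom, wall = 0) {
    g <- zpad_center(a, bottom, "free_slip", wall)
    list(x = (shift_p(a, 1, 1) - shift_p(a, 1, -1)) / d2,
         y = (shift_p(a, 2, 1) - shift_p(a, 2, -1)) / d2,
         z = (g[, , 3:(nz + 2), drop = FALSE] -
                g[, , 1:nz, drop = FALSE]) / d2)
  }
  gu <- grad_c(uc, "no_slip", wall_u)
  gv <- grad_c(vc, "no_slip", wall_v)
  gw <- grad_c(wc, "no_slip", 0)  # w is 0 on both walls
  list(list(dudx, gu$y, gu$z),
       list(gv$x, dvdy, gv$z),
       list(gw$x, gw$y, dwdz))
}

# divergence of the (total) symmetric stress, evaluated at the velocity
# stagger locations; tau uses zero z ghosts (stress vanishes at the top
# interface and throughout the PCL near the wall)
stress_divergence <- function(T6, h) {
  nz <- dim(T6$xx)[3]
  corner_xy <- function(a) (a + shift_p(a, 1, 1) + shift_p(a, 2, 1) +
                              shift_p(shift_p(a, 1, 1), 2, 1)) / 4
  padz <- function(a) zpad_center(a, "zero", "zero")
  # x faces
  fx <- (shift_p(T6$xx, 1, 1) - T6$xx) / h
  cxy <- corner_xy_x(T6$xy)
  fx <- fx + (cxy - shift_p(cxy, 2, -1)) / h
  xzp <- padz(T6$xz)
  xz_face <- (xzp[, , 1:(nz + 1), drop = FALSE] +
                xzp[, , 2:(nz + 2), drop = FALSE] +
                shift_p(xzp, 1, 1)[, , 1:(nz + 1), drop = FALSE] +
                shift_p(xzp, 1, 1)[, , 2:(nz + 2), drop = FALSE]) / 4
  fx <- fx + (xz_face[, , 2:(nz + 1), drop = FALSE] -
                xz_face[, , 1:nz, drop = FALSE]) / h
  # y faces
  fy <- (shift_p(T6$yy, 2, 1) - T6$yy) / h
  cyx <- corner_xy_y(T6$xy)
  fy <- fy + (cyx - shift_p(cyx, 1, -1)) / h
  yzp <- padz(T6$yz)
  yz_face <- (yzp[, , 1:(nz + 1), drop = FALSE] +
                yzp[, , 2:(nz + 2), drop = FALSE] +
                shift_p(yzp, 2, 1)[, , 1:(nz + 1), drop = FALSE] +
                shift_p(yzp, 2, 1)[, , 2:(nz + 2), drop = FALSE]) / 4
  fy <- fy + (yz_face[, , 2:(nz + 1), drop = FALSE] -
                yz_face[, , 1:nz, drop = FALSE]) / h
  # z faces
  fz <- array(0, c(dim(T6$xx)[1], dim(T6$xx)[2], nz + 1))
  if (nz >= 2) {
    ks <- 2:nz
    xz_c <- (T6$xz[, , ks - 1, drop = FALSE] +
               T6$xz[, , ks, drop = FALSE]) / 2   # at (i, j, k-1/2)
    xz_cx <- (shift_p(xz_c, 1, 1) - shift_p(xz_c, 1, -1)) / (2 * h)
    yz_c <- (T6$yz[, , ks - 1, drop = FALSE] +
               T6$yz[, , ks, drop = FALSE]) / 2
    yz_cy <- (shift_p(yz_c, 2, 1) - shift_p(yz_c, 2, -1)) / (2 * h)
    dzz <- (T6$zz[, , ks, drop = FALSE] -
              T6$zz[, , ks - 1, drop = FALSE]) / h
    fz[, , ks] <- xz_cx + yz_cy + dzz
  }
  list(x = fx, y = fy, z = fz)
}

# tau_xy averaged to the (i+1/2, j+1/2) corner
corner_xy_x <- function(a) (a + shift_p(a, 1, 1) + shift_p(a, 2, 1) +
                              shift_p(shift_p(a, 1, 1), 2, 1)) / 4
corner_xy_y <- function(a) corner_xy_x(a)

## ---- time stepping --------------------------------------------------------

#' Stable flow time step
#'
#' Returns the explicit stability limit combining the advective CFL, the
#' modal elastic shear-wave CFL `h / sqrt(eta_p / (rho lambda))` and the
#' fastest stress relaxation time; the Newtonian viscous term is integrated
#' implicitly and does not constrain the step.
#'
#' @param state a [flow_state()].
#' @param cfl safety factor.
#' @return time step (s).
#' @export
flow_dt <- function(state, cfl = 0.4) {
  h <- state$grid$h
  umax <- max(abs(state$u), abs(state$v), abs(state$w), 1e-12)
  dt <- cfl * h / umax
  if (!is.null(state$giesekus)) {
    gp <- state$giesekus
    c_el <- sqrt(max(gp$eta_p / (state$fluid$rho * gp$lambda)))
    dt <- min(dt, cfl * h / c_el, 0.5 * min(gp$lambda))
  }
  dt
}

#' Enforce the flow boundary conditions
#'
#' z-normal velocity pinned to zero on both walls (no penetration at the
#' epithelium, flat free-slip air-mucus interface) and the elastic stress
#' masked to zero below the PCL-mucus interface and in the top boundary
#' layer; periodic x'/y' conditions are implicit in the array storage, and
#' the tangential-velocity wall/interface conditions enter through the ghost
#' layers of each operator.
#'
#' @param state a [flow_state()].
#' @return the corrected state.
#' @export
apply_flow_bcs <- function(state) {
  nzp <- dim(state$w)[3]
  state$w[, , 1] <- 0
  state$w[, , nzp] <- 0
  if (!is.null(state$tau)) {
    m <- state$mucus_mask
    for (a in seq_along(state$tau)) {
      for (k in names(state$tau[[a]])) {
        state$tau[[a]][[k]] <- state$tau[[a]][[k]] * m
      }
    }
  }
  state
}

#' Advance the ASL flow by one time step
#'
#' One projection step: explicit Giesekus stress update in the mucus layer,
#' momentum predictor (central advection, Crank-Nicolson Newtonian
#' diffusion via FFT-tridiagonal Helmholtz solves, explicit elastic stress
#' divergence), direct-forcing immersed-boundary correction that imposes the
#' cilium surface velocity at the Lagrangian markers, pressure Poisson
#' solve, projection to a discretely divergence-free field and boundary
#' re-enforcement.
#'
#' @param state a [flow_state()].
#' @param markers optional [cilia_markers()] (positions `X`, velocities `U`,
#'   volumes `dV`) carrying the beat kinematics at the current time.
#' @param dt time step (s); [flow_dt()] default.
#' @param wall_u bottom-wall x velocity (m/s), for wall-driven verification
#'   problems; 0 for the resting epithelium.
#' @param n_forcing_iter direct-forcing passes (1 = classical direct
#'   forcing; more approximate the multidirect limit).
#' @return the advanced `flow_state`; attribute `div_max` records the
#'   post-projection maximum divergence.
#' @export
step_flow <- function(state, markers = NULL, dt = NULL, wall_u = 0,
                      n_forcing_iter = 1) {
  g <- state$grid; h <- g$h
  nu <- state$fluid$nu; rho <- state$fluid$rho
  if (is.null(dt)) dt <- flow_dt(state)
  nz <- g$nz
  umax <- max(abs(state$u), abs(state$v), abs(state$w))
  if (umax * dt / h > 1) {
    stop(sprintf("advective CFL violated (%.2f); use dt <= %.3g s",
                 umax * dt / h, 0.4 * h / umax))
  }

  # --- elastic stress update (explicit, mucus only) ---
  ftau <- list(x = 0, y = 0, z = 0)
  if (!is.null(state$tau)) {
    L <- velocity_gradient(state$u, state$v, state$w, h, wall_u)
    uc <- (state$u + shift_p(state$u, 1, -1)) / 2
    vc <- (state$v + shift_p(state$v, 2, -1)) / 2
    wc <- (state$w[, , 1:nz, drop = FALSE] +
             state$w[, , 2:(nz + 1), drop = FALSE]) / 2
    gp <- state$giesekus
    total <- tensor_zero(dim(state$p))
    for (a in seq_len(gp$n_modes)) {
      adv <- stress_advection(state$tau[[a]], uc, vc, wc, h)
      state$tau[[a]] <- giesekus_mode_step(
        state$tau[[a]], L, dt, gp$lambda[a], gp$eta_p[a], gp$alpha[a],
        adv = adv)
      for (k in names(total)) {
        state$tau[[a]][[k]] <- state$tau[[a]][[k]] * state$mucus_mask
        total[[k]] <- total[[k]] + state$tau[[a]][[k]]
      }
    }
    ftau <- stress_divergence(total, h)
    ftau <- list(x = ftau$x / rho, y = ftau$y / rho, z = ftau$z / rho)
  }

  # --- momentum predictor with Crank-Nicolson Newtonian diffusion ---
  adv <- advection_terms(state$u, state$v, state$w, h, wall_u)
  a_cn <- nu * dt / 2
  rhs_u <- state$u + dt * (-adv$u + ftau$x) +
    a_cn * laplacian_center(state$u, h, "no_slip", "free_slip", wall_u)
  rhs_v <- state$v + dt * (-adv$v + ftau$y) +
    a_cn * laplacian_center(state$v, h, "no_slip", "free_slip", 0)
  rhs_w <- state$w + dt * (-adv$w + ftau$z) +
    a_cn * laplacian_face(state$w, h)
  # wall-velocity contribution to the implicit ghost at k = 1
  if (wall_u != 0) rhs_u[, , 1] <- rhs_u[, , 1] + 2 * a_cn * wall_u / h^2
  u_star <- helmholtz_center(rhs_u, a_cn, h)
  v_star <- helmholtz_center(rhs_v, a_cn, h)
  w_star <- helmholtz_face(rhs_w, a_cn, h)

  # --- direct-forcing IBM: impose beat velocities at the markers ---
  if (!is.null(markers) && nrow(markers$X) > 0) {
    U <- markers$U; dV <- markers$dV
    ops <- markers$ops
    if (is.null(ops)) {
      ops <- marker_flow_ops(markers$X, dV, h, dim(u_star), dim(w_star))
    }
    for (it in seq_len(n_forcing_iter)) {
      Fu <- (U[, 1] - ibm_interpolate(u_star, ops$u)) / (dt * ops$u$G)
      Fv <- (U[, 2] - ibm_interpolate(v_star, ops$v)) / (dt * ops$v$G)
      Fw <- (U[, 3] - ibm_interpolate(w_star, ops$w)) / (dt * ops$w$G)
      u_star <- u_star + dt * ibm_spread(Fu, dV, ops$u)
      v_star <- v_star + dt * ibm_spread(Fv, dV, ops$v)
      w_star <- w_star + dt * ibm_spread(Fw, dV, ops$w)
    }
  }
  w_star[, , 1] <- 0
  w_star[, , nz + 1] <- 0

  # --- projection ---
  div <- flow_divergence(u_star, v_star, w_star, h)
  phi <- poisson_neumann(div / dt, h)
  state$u <- u_star - dt * (shift_p(phi, 1, 1) - phi) / h
  state$v <- v_star - dt * (shift_p(phi, 2, 1) - phi) / h
  wn <- w_star
  if (nz >= 2) {
    ks <- 2:nz
    wn[, , ks] <- w_star[, , ks, drop = FALSE] -
      dt * (phi[, , ks, drop = FALSE] - phi[, , ks - 1, drop = FALSE]) / h
  }
  state$w <- wn
  state$p <- rho * phi
  state <- apply_flow_bcs(state)
  state$t <- state$t + dt
  attr(state, "div_max") <- max(abs(flow_divergence(state$u, state$v,
                                                    state$w, h)))
  state
}

# sparse transfer operators of a marker cloud against the three velocity
# staggers, with collective-gain normalization baked in
marker_flow_ops <- function(X, dV, h, dims_uv, dims_w) {
  st_u <- ibm_stencil(X, c(h, h / 2, h / 2), h, dims_uv,
                      zfold = "odd", zstag = "center")
  st_v <- ibm_stencil(X, c(h / 2, h, h / 2), h, dims_uv,
                      zfold = "odd", zstag = "center")
  st_w <- ibm_stencil(X, c(h / 2, h / 2, 0), h, dims_w,
                      zfold = "odd", zstag = "face")
  list(u = ibm_operator(st_u, dV),
       v = ibm_operator(st_v, dV),
       w = ibm_operator(st_w, dV))
}

# u.grad(tau) at cell centres, zero z ghosts (stress masked near walls)
stress_advection <- function(tau, uc, vc, wc, h) {
  nz <- dim(uc)[3]
  d2 <- 2 * h
  out <- tau
  for (k in names(tau)) {
    a <- tau[[k]]
    g <- zpad_center(a, "zero", "zero")
    out[[k]] <- uc * (shift_p(a, 1, 1) - shift_p(a, 1, -1)) / d2 +
      vc * (shift_p(a, 2, 1) - shift_p(a, 2, -1)) / d2 +
      wc * (g[, , 3:(nz + 2), drop = FALSE] -
              g[, , 1:nz, drop = FALSE]) / d2
  }
  out
}

#' Volume-averaged x' velocity of an ASL layer
#'
#' @param state a [flow_state()] (or a u-array with a grid).
#' @param layer `"PCL"` (below the interface), `"mucus"` (above it) or
#'   `"ASL"` (whole depth).
#' @param grid required when `state` is a bare array.
#' @return mean x' velocity in um/s.
#' @export
layer_average_velocity <- function(state, layer = c("ASL", "mucus", "PCL"),
                                   grid = NULL) {
  layer <- match.arg(layer)
  if (inherits(state, "flow_state")) {
    u <- state$u; grid <- state$grid
  } else {
    u <- state
    stopifnot(!is.null(grid))
  }
  uc <- (u + shift_p(u, 1, -1)) / 2
  zc <- grid$zc
  keep <- switch(layer,
    PCL = zc < grid$z_interface,
    mucus = zc >= grid$z_interface,
    ASL = rep(TRUE, length(zc)))
  m_to_um(mean(uc[, , keep]))
}

#' Run the flow over beat cycles and record one replay cycle
#'
#' Advances the coupled cilia-ASL flow for `n_spinup` beat cycles and then
#' records `n_snapshots` evenly spaced velocity snapshots over one further
#' cycle. Because the cilia forcing is exactly beat-periodic and the drug
#' does not feed back on the flow, long transport episodes replay this
#' cycle periodically instead of re-solving the flow.
#'
#' @param lattice a [build_lattice()].
#' @param grid a [grid_spec()].
#' @param fluid,giesekus fluid and mucus rheology parameters.
#' @param n_spinup spin-up beat cycles before recording.
#' @param n_snapshots snapshots recorded over the final cycle.
#' @param dt time step; [flow_dt()] limit by default.
#' @param n_marker_bins beat-phase bins at which marker positions,
#'   velocities and transfer operators are precomputed and reused (the beat
#'   is sampled at this cadence, consistent with the snapshot replay).
#' @param n_forcing_iter direct-forcing passes per step.
#' @param verbose print per-cycle diagnostics.
#' @return object of class `flow_cycle`: snapshot times (phases) and `u`,
#'   `v`, `w` arrays per snapshot, plus the final state.
#' @export
run_flow_cycle <- function(lattice, grid, fluid = fluid_props(),
                           giesekus = giesekus_params(), n_spinup = 2,
                           n_snapshots = 16, dt = NULL, n_marker_bins = 96,
                           n_forcing_iter = 2, verbose = FALSE) {
  state <- flow_state(grid, fluid, giesekus)
  T_c <- 1 / lattice$frequency
  y0 <- grid$Ly / 2
  if (is.null(dt)) {
    tip <- 2 * pi * lattice$length * lattice$frequency
    probe <- state; probe$u[1] <- tip
    dt <- flow_dt(probe)
  }
  n_per_cycle <- ceiling(T_c / dt)
  dt <- T_c / n_per_cycle
  dims_uv <- c(grid$nx, grid$ny, grid$nz)
  dims_w <- c(grid$nx, grid$ny, grid$nz + 1)
  bins <- lapply(seq_len(n_marker_bins), function(b) {
    tb <- (b - 1) / n_marker_bins * T_c
    mk <- cilia_markers(lattice, tb, grid$h, y0)
    mk$ops <- marker_flow_ops(mk$X, mk$dV, grid$h, dims_uv, dims_w)
    mk
  })
  snap_every <- max(1L, floor(n_per_cycle / n_snapshots))
  snaps <- list(); snap_phase <- numeric(0)
  total_cycles <- n_spinup + 1
  for (cyc in seq_len(total_cycles)) {
    for (i in seq_len(n_per_cycle)) {
      b <- (floor((state$t / T_c) * n_marker_bins + 1e-9) %%
              n_marker_bins) + 1
      state <- step_flow(state, bins[[b]], dt,
                         n_forcing_iter = n_forcing_iter)
      if (cyc == total_cycles && (i - 1) %% snap_every == 0 &&
          length(snaps) < n_snapshots) {
        snaps[[length(snaps) + 1]] <- list(u = state$u, v = state$v,
                                           w = state$w)
        snap_phase <- c(snap_phase, ((i - 1) / n_per_cycle))
      }
    }
    if (verbose) {
      message(sprintf(
        "cycle %d/%d: mucus %.1f um/s, PCL %.1f um/s, max|div| %.2e",
        cyc, total_cycles, layer_average_velocity(state, "mucus"),
        layer_average_velocity(state, "PCL"), attr(state, "div_max")))
    }
  }
  structure(list(snapshots = snaps, phase = snap_phase, T_c = T_c,
                 grid = grid, lattice = lattice, dt = dt,
                 final_state = state), class = "flow_cycle")
}

#' Velocity field at an arbitrary time from a recorded cycle
#'
#' Periodic linear interpolation between the stored snapshots.
#'
#' @param cycle a [run_flow_cycle()] result.
#' @param t time (s).
#' @return list of `u`, `v`, `w` arrays.
#' @export
flow_at_time <- function(cycle, t) {
  ph <- (t / cycle$T_c) %% 1
  phases <- cycle$phase
  n <- length(phases)
  i0 <- findInterval(ph, phases)
  if (i0 < 1) i0 <- n
  i1 <- if (i0 == n) 1L else i0 + 1L
  p0 <- phases[i0]
  p1 <- if (i1 == 1L) phases[1] + 1 else phases[i1]
  wgt <- if (p1 > p0) (ph - p0) / (p1 - p0) else 0
  if (wgt < 0) wgt <- wgt + 1 / (p1 - p0) * 0  # ph below first phase: wrap
  s0 <- cycle$snapshots[[i0]]; s1 <- cycle$snapshots[[i1]]
  list(u = s0$u * (1 - wgt) + s1$u * wgt,
       v = s0$v * (1 - wgt) + s1$v * wgt,
       w = s0$w * (1 - wgt) + s1$w * wgt)
}
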