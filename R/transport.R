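#' Three-step Runge-Kutta coefficients
#'
#' Coefficients of the explicit low-storage three-substep Runge-Kutta
#' scheme used for the convection-diffusion update: `gamma = (8/15, 5/12,
#' 3/4)`, `zeta = (0, -17/60, -5/12)`. Their sums satisfy
#' `sum(gamma + zeta) = 1` (consistency) and each substep combines the
#' operator at the current and previous substep states.
#'
#' @return list with `gamma`, `zeta` and `n_mass_iter` (the default number
#'   of iterated immersed-boundary mass-source corrections, 4).
#' @export
rk3_coefficients <- function() {
  list(gamma = c(8 / 15, 5 / 12, 3 / 4),
       zeta = c(0, -17 / 60, -5 / 12),
       n_mass_iter = 4L)
}

#' Transport boundary conditions as ghost layers
#'
#' Builds the ghost-augmented concentration array that encodes the
#' transport boundary conditions: a uniform Neumann dissolution flux at the
#' air-mucus interface (`D dc/dz = m''_d`, ghost `= c_top + h m''_d / D`),
#' a perfect-sink epithelium (`c = 0` at the wall, ghost `= -c_1`) and
#' periodic x'/y' (implicit in the array storage).
#'
#' @param c concentration array (kg/m3).
#' @param flux_top dissolution mass flux `m''_d` (kg/m2/s).
#' @param D diffusivity (m2/s).
#' @param h grid spacing (m).
#' @return array with two extra z layers (ghosts at 1 and nz+2).
#' @export
apply_transport_bcs <- function(c, flux_top, D, h) {
  d <- dim(c); nz <- d[3]
  g <- array(0, c(d[1], d[2], nz + 2))
  g[, , 2:(nz + 1)] <- c
  g[, , 1] <- -c[, , 1]
  g[, , nz + 2] <- c[, , nz] + h * flux_top / D
  g
}

# convection-diffusion right-hand side in conservative form.
# Returns the rate array plus the instantaneous boundary bookkeeping:
# top influx (kg/s) and bottom (epithelial) outflux (kg/s) of the same
# discrete operator, so the ledger closes to round-off.
transport_rhs <- function(c, vel, D, h, flux_top) {
  d <- dim(c); nz <- d[3]
  g <- apply_transport_bcs(c, flux_top, D, h)
  lap <- (shift_p(c, 1, 1) + shift_p(c, 1, -1) +
            shift_p(c, 2, 1) + shift_p(c, 2, -1) - 4 * c +
            g[, , 3:(nz + 2), drop = FALSE] +
            g[, , 1:nz, drop = FALSE] - 2 * c) / h^2
  rate <- D * lap
  if (!is.null(vel)) {
    u <- vel$u; v <- vel$v; w <- vel$w
    Fx <- u * (c + shift_p(c, 1, 1)) / 2          # flux through x face i+1/2
    Fy <- v * (c + shift_p(c, 2, 1)) / 2
    Fz <- array(0, c(d[1], d[2], nz + 1))
    if (nz >= 2) {
      ks <- 2:nz
      Fz[, , ks] <- w[, , ks, drop = FALSE] *
        (c[, , ks - 1, drop = FALSE] + c[, , ks, drop = FALSE]) / 2
    }
    rate <- rate - (Fx - shift_p(Fx, 1, -1) + Fy - shift_p(Fy, 2, -1) +
                      Fz[, , 2:(nz + 1), drop = FALSE] -
                      Fz[, , 1:nz, drop = FALSE]) / h
  }
  A_cell <- h^2
  list(rate = rate,
       influx = flux_top * d[1] * d[2] * A_cell,
       outflux = sum(2 * D * c[, , 1] / h) * A_cell)
}

#' One provisional RK3 substep of the transport solver
#'
#' `c* = c^(s-1) + dt (gamma_s Op[c^(s-1)] + zeta_s Op[c^(s-2)])` with the
#' convection-diffusion operator discretized by second-order central
#' differences in conservative form.
#'
#' @param c_prev concentration at substep `s-1`.
#' @param rhs_prev operator evaluation at `s-1` (from the internal RHS).
#' @param rhs_prev2 operator evaluation at `s-2` (`NULL` for `s = 1`).
#' @param dt full time step (s).
#' @param s substep index 1..3.
#' @return provisional concentration array.
#' @export
rk3_substep <- function(c_prev, rhs_prev, rhs_prev2, dt, s) {
  co <- rk3_coefficients()
  out <- c_prev + dt * co$gamma[s] * rhs_prev
  if (s > 1 && !is.null(rhs_prev2)) out <- out + dt * co$zeta[s] * rhs_prev2
  out
}

#' Iterated immersed-boundary attachment source
#'
#' Applies the ciliary drug-attachment correction to a provisional
#' concentration field: the concentration is interpolated to the cilium
#' surface markers, the target marker concentration is set to
#' `(1 - kappa_att) * C_l*` (full attachment, the `C_l = 0` limit, at
#' `kappa_att = 1`; no attachment at 0), and the mass source
#' `Q_l = (C_l - C_l*) / dt` is spread back and iterated `n_iter` times to
#' sharpen the imposed marker concentration.
#'
#' @param c_star provisional concentration array.
#' @param stencil [ibm_stencil()] or [ibm_operator()] of the markers on the
#'   concentration grid. An operator carries the collective-gain
#'   normalization `G` that makes the iteration contract rapidly even for
#'   under-resolved markers.
#' @param dV per-marker element volumes (m3).
#' @param kappa_att attachment strength in `[0, 1]`.
#' @param dt full time step (s).
#' @param n_iter mass-source iterations (default 4).
#' @return list: `c` (corrected field), `Q` (final per-marker sources,
#'   kg/m3/s), `attached` (mass attached this substep, kg, `>= 0` for
#'   `kappa_att > 0`).
#' @export
attachment_iteration <- function(c_star, stencil, dV, kappa_att, dt,
                                 n_iter = 4) {
  stopifnot(kappa_att >= 0, kappa_att <= 1)
  if (kappa_att == 0 || is.null(stencil)) {
    return(list(c = c_star, Q = NULL, attached = 0))
  }
  G <- if (inherits(stencil, "ibm_operator")) stencil$G else 1
  Cl_star <- ibm_interpolate(c_star, stencil)
  Cl_target <- (1 - kappa_att) * Cl_star
  Q <- (Cl_target - Cl_star) / (dt * G)
  cc <- c_star + dt * ibm_spread(Q, dV, stencil)
  for (i in seq_len(n_iter)) {
    Cl_i <- ibm_interpolate(cc, stencil)
    Q <- Q + (Cl_target - Cl_i) / (dt * G)
    cc <- c_star + dt * ibm_spread(Q, dV, stencil)
  }
  attached <- -sum(Q * dV) * dt
  list(c = cc, Q = Q, attached = attached)
}

#' Run a drug-transport episode
#'
#' Full one-way-coupled episode: Noyes-Whitney dissolution of a single
#' deposited particle feeds a uniform mass flux into the top of the ASL
#' strip; the concentration field is advanced by the three-substep
#' Runge-Kutta convection-diffusion scheme using a periodically replayed
#' beat cycle of the flow; cilium surface markers remove drug through the
#' iterated attachment source; the epithelial base absorbs perfectly. Mass
#' ledgers (injected, in-domain, deposited, attached) are closed against
#' the same discrete operators at every step.
#'
#' @param grid a [grid_spec()].
#' @param drug a [drug_spec()] or name.
#' @param flow optional [run_flow_cycle()] result replayed periodically;
#'   `NULL` runs pure diffusion (quiescent film).
#' @param lattice optional [build_lattice()]; required when
#'   `kappa_att > 0` (the markers define where attachment happens).
#' @param kappa_att per-substep marker attachment strength in `[0, 1]`.
#' @param diameter_um initial particle diameter (um).
#' @param deposition_area_um2 area (um2) over which one particle's
#'   dissolved mass is spread; defaults to the full cilia-lattice tile
#'   `(wavelength)^2` when a lattice is given, else the strip top area.
#' @param dt time step (s); defaults to the diffusive stability limit with
#'   a 0.4 safety factor (and the advective CFL when flow is replayed).
#' @param t_end hard stop (s); by default runs until 99.9% of the
#'   (area-scaled) particle mass is deposited or attached.
#' @param record_every record the metrics series every this many steps.
#' @param n_phase_bins number of beat-phase bins at which marker stencils
#'   are cached for the attachment source.
#' @param n_mass_iter mass-source iterations per substep.
#' @return object of class `transport_result`: a data.frame `series` with
#'   columns `t`, `dissolved_frac`, `deposited_frac`, `attached_frac`,
#'   `in_domain_frac`, `Cb`, `car`, and summary fields (ledgers, achieved
#'   CAR, mass-budget drift, minimum concentration seen).
#' @export
run_transport <- function(grid, drug, flow = NULL, lattice = NULL,
                          kappa_att = 0, diameter_um = 5,
                          deposition_area_um2 = NULL, dt = NULL,
                          t_end = Inf, record_every = 25L,
                          n_phase_bins = 32L, n_mass_iter = 4L) {
  if (is.character(drug)) drug <- drug_spec(drug)
  stopifnot(inherits(grid, "grid_spec"), kappa_att >= 0, kappa_att <= 1)
  h <- grid$h; D <- drug$D
  if (is.null(deposition_area_um2)) {
    deposition_area_um2 <- if (!is.null(lattice)) {
      m_to_um(lattice$wavelength)^2
    } else {
      m_to_um(grid$Lx) * m_to_um(grid$Ly)
    }
  }
  A_dep <- deposition_area_um2 * 1e-12
  A_strip <- grid$Lx * grid$Ly
  if (is.null(dt)) {
    dt <- 0.4 * h^2 / (6 * D)
    if (!is.null(flow)) {
      umax <- max(vapply(flow$snapshots, function(s)
        max(abs(s$u), abs(s$v), abs(s$w)), numeric(1)))
      if (umax > 0) dt <- min(dt, 0.4 * h / umax)
    }
  }
  particle <- particle_state(drug, diameter_um)
  m0_strip <- particle$m0 * A_strip / A_dep   # reference mass in the strip
  cfield <- array(0, c(grid$nx, grid$ny, grid$nz))
  co <- rk3_coefficients()
  use_markers <- kappa_att > 0 && !is.null(lattice)
  phase_cache <- NULL
  if (use_markers) {
    T_c <- 1 / lattice$frequency
    phase_cache <- lapply(seq_len(n_phase_bins), function(b) {
      tb <- (b - 1) / n_phase_bins * T_c
      mk <- cilia_markers(lattice, tb, h, grid$Ly / 2)
      st <- ibm_stencil(mk$X, c(h / 2, h / 2, h / 2), h, dim(cfield),
                        zfold = "even", zstag = "center")
      list(st = ibm_operator(st, mk$dV), dV = mk$dV)
    })
  }
  cell_vol <- h^3
  injected <- 0; deposited <- 0; attached <- 0
  cmin_seen <- 0
  t <- 0; step <- 0L
  rec <- list()
  exposure <- 0    # cumulative drug mass interpolated onto the cilia
  push_rec <- function() {
    in_dom <- sum(cfield) * cell_vol
    rec[[length(rec) + 1L]] <<- data.frame(
      t = t,
      dissolved_frac = particle$dissolved / particle$m0,
      deposited_frac = deposited / m0_strip,
      attached_frac = attached / m0_strip,
      in_domain_frac = in_dom / m0_strip,
      Cb = mean(cfield),
      car = if (exposure > 0) attached / exposure else 0)
  }
  push_rec()
  budget_drift <- 0
  repeat {
    step <- step + 1L
    Cb <- mean(cfield)
    # dissolution feeds the top flux, held over the step
    dis_before <- particle$dissolved
    if (particle$r > 0) particle <- advance_particle(particle, Cb, dt)
    else particle$t <- particle$t + dt
    md <- (particle$dissolved - dis_before) / dt
    flux_top <- surface_flux(md, A_dep)
    # marker cache bin for this step
    st <- NULL; dV <- NULL
    if (use_markers) {
      b <- (floor((t / (1 / lattice$frequency)) * n_phase_bins) %%
              n_phase_bins) + 1
      st <- phase_cache[[b]]$st; dV <- phase_cache[[b]]$dV
    }
    rhs_prev2 <- NULL
    stage_t <- t
    for (s in 1:3) {
      vel <- if (!is.null(flow)) flow_at_time(flow, stage_t) else NULL
      rhs <- transport_rhs(cfield, vel, D, h, flux_top)
      c_star <- rk3_substep(cfield, rhs$rate, rhs_prev2$rate, dt, s)
      injected <- injected + dt * (co$gamma[s] * rhs$influx +
        if (s > 1) co$zeta[s] * rhs_prev2$influx else 0)
      deposited <- deposited + dt * (co$gamma[s] * rhs$outflux +
        if (s > 1) co$zeta[s] * rhs_prev2$outflux else 0)
      if (use_markers) {
        Cl_star <- ibm_interpolate(c_star, st)
        exposure <- exposure + sum(pmax(Cl_star, 0) * dV)
        att <- attachment_iteration(c_star, st, dV, kappa_att, dt,
                                    n_iter = n_mass_iter)
        c_star <- att$c
        attached <- attached + att$attached
      }
      rhs_prev2 <- rhs
      cfield <- c_star
      stage_t <- t + dt * sum(co$gamma[1:s] + co$zeta[1:s])
    }
    t <- t + dt
    cmin_seen <- min(cmin_seen, min(cfield))
    in_dom <- sum(cfield) * cell_vol
    budget_drift <- abs(injected - deposited - attached - in_dom) /
      max(m0_strip, injected)
    if (step %% record_every == 0L) push_rec()
    done <- (deposited + attached) >= 0.999 * m0_strip ||
      t >= t_end
    if (done) { push_rec(); break }
    if (t > 1e4) stop("transport episode failed to terminate")
  }
  series <- do.call(rbind, rec)
  structure(list(
    series = series,
    drug = drug$name, kappa_att = kappa_att,
    injected = injected, deposited = deposited, attached = attached,
    in_domain = sum(cfield) * cell_vol,
    m0_strip = m0_strip,
    total_deposition_fraction = 100 * deposited / m0_strip,
    attached_fraction = 100 * attached / m0_strip,
    achieved_car = if (exposure > 0) attached / exposure else 0,
    mass_budget_drift = budget_drift,
    min_concentration = cmin_seen,
    t_final = t, dt = dt,
    dissolution_time = if (particle$r <= 0) {
      particle$t_dissolved %||% particle$t
    } else NA_real_
  ), class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf(
    "<transport_result> %s, kappa_att = %g\n  deposited %.1f%%, attached %.1f%% (CAR %.2e), budget drift %.1e\n",
    x$drug, x$kappa_att, x$total_deposition_fraction, x$attached_fraction,
    x$achieved_car, x$mass_budget_drift))
  invisible(x)
}

#' Calibrate the attachment strength to a target ciliary attachment ratio
#'
#' The ciliary attachment ratio (CAR = attached mass / cumulative drug
#' exposure on the cilia) is a measured output of a run; the mechanistic
#' knob is `kappa_att`. This helper bisects `kappa_att` so the achieved CAR
#' matches a target.
#'
#' @param target_car desired CAR.
#' @param ... passed to [run_transport()] (grid, drug, flow, lattice, ...).
#' @param kappa_hi upper bracket for the bisection.
#' @param iters bisection iterations.
#' @return list with `kappa_att`, `achieved_car` and the final run.
#' @export
calibrate_car <- function(target_car, ..., kappa_hi = 1, iters = 8) {
  lo <- 0; hi <- kappa_hi; run <- NULL
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    run <- run_transport(kappa_att = mid, ...)
    if (run$achieved_car < target_car) lo <- mid else hi <- mid
  }
  list(kappa_att = (lo + hi) / 2, achieved_car = run$achieved_car,
       run = run)
}
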