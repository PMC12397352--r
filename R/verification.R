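#' Analytic 1D convection-diffusion benchmark
#'
#' The classical moving-Gaussian solution of
#' `dc/dt + kappa dc/dx = beta d2c/dx2` on `[0, 1]` with
#' `c(x, 0) = exp(-(x-2)^2/8)`, time-dependent Dirichlet boundary data
#' taken from the exact solution
#' `c(x, t) = sqrt(20/(20+t)) exp(-(x - 2 - 0.8 t)^2 / (0.4 (t + 20)))`
#' for `kappa = 0.8`, `beta = 0.1`.
#'
#' @param x positions.
#' @param t time (s).
#' @param kappa advection speed.
#' @param beta diffusivity.
#' @return exact concentration values.
#' @export
analytic_case_exact <- function(x, t, kappa = 0.8, beta = 0.1) {
  # general form for IC exp(-(x-x0)^2/(4 beta t0)) advected at kappa
  x0 <- 2; t0 <- 8 / (4 * beta)   # 8 = 4 beta t0 -> t0 = 20
  sqrt(t0 / (t0 + t)) * exp(-(x - x0 - kappa * t)^2 / (4 * beta * (t0 + t)))
}

#' Solve the analytic benchmark with the transport kernel
#'
#' Advances the 1D convection-diffusion equation with the same three-step
#' Runge-Kutta time integrator and second-order central differences as the
#' 3D transport solver, using exact Dirichlet boundary values, and compares
#' against the closed-form solution.
#'
#' @param n_cells interior grid cells on `[0, 1]` (node-based grid).
#' @param t_end final time; conventionally 0.1, 0.4 or 0.8.
#' @param dt time step; defaults to a diffusive limit with safety 0.25.
#' @param kappa,beta advection speed and diffusivity.
#' @return list with `x`, `numeric`, `exact`, `max_rel_error`.
#' @export
solve_analytic_case <- function(n_cells = 512, t_end = 0.8, dt = NULL,
                                kappa = 0.8, beta = 0.1) {
  stopifnot(n_cells >= 8, t_end > 0)
  nx <- n_cells + 1
  x <- seq(0, 1, length.out = nx)
  hx <- x[2] - x[1]
  if (is.null(dt)) dt <- 0.25 * hx^2 / (2 * beta)
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps
  co <- rk3_coefficients()
  cnum <- analytic_case_exact(x, 0, kappa, beta)
  rhs_op <- function(cv, t_now) {
    # Dirichlet ends from the exact boundary data
    cb <- cv
    cb[1] <- analytic_case_exact(0, t_now, kappa, beta)
    cb[nx] <- analytic_case_exact(1, t_now, kappa, beta)
    i <- 2:(nx - 1)
    r <- numeric(nx)
    r[i] <- -kappa * (cb[i + 1] - cb[i - 1]) / (2 * hx) +
      beta * (cb[i + 1] - 2 * cb[i] + cb[i - 1]) / hx^2
    list(rate = r, cb = cb)
  }
  t_now <- 0
  for (n in seq_len(nsteps)) {
    rhs_prev2 <- NULL
    stage_t <- t_now
    cv <- cnum
    for (s in 1:3) {
      ev <- rhs_op(cv, stage_t)
      cv <- ev$cb + dt * co$gamma[s] * ev$rate +
        if (s > 1) dt * co$zeta[s] * rhs_prev2$rate else 0
      rhs_prev2 <- ev
      stage_t <- t_now + dt * sum(co$gamma[1:s] + co$zeta[1:s])
      cv[1] <- analytic_case_exact(0, stage_t, kappa, beta)
      cv[nx] <- analytic_case_exact(1, stage_t, kappa, beta)
    }
    cnum <- cv
    t_now <- t_now + dt
  }
  exact <- analytic_case_exact(x, t_end, kappa, beta)
  list(x = x, numeric = cnum, exact = exact,
       max_rel_error = max(abs(cnum - exact) / abs(exact)),
       n_cells = n_cells, dt = dt)
}

#' Grid-refinement study on the analytic benchmark
#'
#' Doubles the resolution until the maximum relative error at `t_end`
#' drops below `target_error`, and reports the observed convergence order
#' from consecutive refinements.
#'
#' @param t_end final time.
#' @param start_n starting resolution.
#' @param target_error stop once the error is below this.
#' @param max_doublings cap on refinements.
#' @return data.frame with `n_cells`, `max_rel_error`, plus attribute
#'   `order` (log2 error-ratio slope between the last two rows).
#' @export
analytic_convergence <- function(t_end = 0.8, start_n = 64,
                                 target_error = 3.5e-6, max_doublings = 6) {
  n <- start_n
  rows <- list()
  for (i in seq_len(max_doublings + 1)) {
    sol <- solve_analytic_case(n_cells = n, t_end = t_end)
    rows[[i]] <- data.frame(n_cells = n, max_rel_error = sol$max_rel_error)
    if (sol$max_rel_error <= target_error) break
    n <- n * 2
  }
  out <- do.call(rbind, rows)
  if (nrow(out) >= 2) {
    k <- nrow(out)
    attr(out, "order") <- log2(out$max_rel_error[k - 1] /
                                 out$max_rel_error[k])
  }
  out
}

#' Miniature deterministic fixtures
#'
#' Named presets used by the property suite and for quick smoke runs; each
#' returns the constructed configuration objects plus the list of
#' machine-checkable properties it is meant to exercise.
#'
#' @param preset `"tiny-flow"` (8x4x12 Newtonian strip, no cilia),
#'   `"single-cilium"` (one cilium on a small strip),
#'   `"tiny-transport"` (coarse strip with 4 cilia) or
#'   `"column-1d"` (zero-velocity diffusion column).
#' @return list with the preset pieces (`grid`, `lattice`, ...) and
#'   `properties`, a character vector describing the checks it supports.
#' @export
make_fixture <- function(preset = c("tiny-flow", "single-cilium",
                                    "tiny-transport", "column-1d")) {
  preset <- match.arg(preset)
  switch(preset,
    "tiny-flow" = list(
      grid = grid_spec(nx = 8, ny = 4, nz = 12),
      lattice = NULL,
      properties = c("quiescence preserved", "divergence bound")),
    "single-cilium" = list(
      grid = grid_spec(nx = 24, ny = 4, nz = 16),
      lattice = build_lattice(n_cilia = 1, wavelength_um = 17 / 16 * 24,
                              length_um = 5, diameter_um = 0.3),
      properties = c("nonzero cycle-averaged mucus velocity",
                     "divergence bound")),
    "tiny-transport" = list(
      grid = grid_spec(nx = 16, ny = 4, nz = 12),
      lattice = build_lattice(n_cilia = 4, wavelength_um = 17 / 12 * 16),
      properties = c("mass budget closure", "attachment monotonicity")),
    "column-1d" = list(
      grid = grid_spec(nx = 1, ny = 1, nz = 32),
      lattice = NULL,
      properties = c("linear steady profile", "deposition rate = influx"))
  )
}
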