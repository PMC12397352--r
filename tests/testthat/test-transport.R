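test_that("RK3 coefficients satisfy the consistency identity", {
  co <- rk3_coefficients()
  expect_equal(sum(co$gamma + co$zeta), 1, tolerance = 1e-15)
  expect_length(co$gamma, 3)
  # the scheme integrates dc/dt = lambda c with third-order accuracy
  lam <- -2.3
  step_rk3 <- function(c0, dt) {
    rhs_prev <- NULL; cv <- c0
    for (s in 1:3) {
      r <- lam * cv
      cv <- cv + dt * co$gamma[s] * r +
        if (s > 1) dt * co$zeta[s] * rhs_prev else 0
      rhs_prev <- r
    }
    cv
  }
  errs <- vapply(c(0.01, 0.005), function(dt) {
    cv <- 1
    for (i in seq_len(round(1 / dt))) cv <- step_rk3(cv, dt)
    abs(cv - exp(lam))
  }, numeric(1))
  expect_gt(log2(errs[1] / errs[2]), 2.7)   # ~3rd order in time
})

test_that("uniform concentration with no flux and no flow is invariant", {
  g <- grid_spec(nx = 6, ny = 4, nz = 10)
  cf <- array(2.5, c(6, 4, 10))
  r <- mucosim:::transport_rhs(cf, NULL, 1e-9, g$h, flux_top = 0)
  # interior untouched; only the absorbing base drains
  expect_equal(max(abs(r$rate[, , 2:10])), 0)
  expect_gt(r$outflux, 0)
})

test_that("steady column under constant influx is linear with matching flux", {
  fx <- make_fixture("column-1d")
  g <- fx$grid
  D <- 4.1e-10
  flux <- 1e-6
  cf <- array(0, c(g$nx, g$ny, g$nz))
  dt <- 0.3 * g$h^2 / (2 * D)
  # march to steady state
  for (i in 1:40000) {
    r <- mucosim:::transport_rhs(cf, NULL, D, g$h, flux)
    cf <- cf + dt * r$rate
  }
  prof <- cf[1, 1, ]
  expect_equal(prof, flux / D * g$zc, tolerance = 1e-3)
  r <- mucosim:::transport_rhs(cf, NULL, D, g$h, flux)
  expect_equal(r$outflux, r$influx, tolerance = 1e-3)
})

test_that("transport boundary ghosts encode flux top and sink base", {
  cf <- array(1, c(2, 2, 5))
  D <- 2e-10; h <- 5e-7; flux <- 3e-6
  gh <- apply_transport_bcs(cf, flux, D, h)
  expect_equal(gh[, , 1], -cf[, , 1])                    # c = 0 at the wall
  expect_equal(gh[, , 7], cf[, , 5] + h * flux / D)      # Neumann influx
})

test_that("attachment iteration contracts the marker concentration", {
  dims <- c(12, 12, 12); h <- 1e-6
  X <- matrix(c(6, 6, 6) * h - h / 2, 1, 3)   # single marker on a node
  st <- ibm_stencil(X, c(h / 2, h / 2, h / 2), h, dims)
  op <- ibm_operator(st, dV = h^3)
  cf <- array(1, dims)
  res <- attachment_iteration(cf, op, dV = h^3, kappa_att = 1, dt = 0.1,
                              n_iter = 4)
  # maximal attachment: interpolated concentration driven near zero
  expect_lt(abs(ibm_interpolate(res$c, op)), 0.05)
  expect_gt(res$attached, 0)
  # the domain loses exactly the spread mass
  expect_equal(sum(cf - res$c) * h^3, res$attached, tolerance = 1e-12)
  # no attachment at kappa = 0
  res0 <- attachment_iteration(cf, op, dV = h^3, kappa_att = 0, dt = 0.1)
  expect_identical(res0$c, cf)
  expect_identical(res0$attached, 0)
})

test_that("quiescent episode reproduces the 1D dissolution-diffusion oracle", {
  # zero-velocity strip vs the independent coupled-column integrator
  g <- grid_spec(nx = 4, ny = 2, nz = 32)
  d <- drug_spec("TIO")
  res <- run_transport(g, d, flow = NULL, lattice = NULL,
                       deposition_area_um2 = 55^2)
  col <- dissolve_in_column(d, nz = 32, deposition_area_um2 = 55^2)
  expect_equal(res$dissolution_time, attr(col, "t_d"), tolerance = 0.02)
  expect_lt(res$mass_budget_drift, 1e-10)
  expect_equal(res$total_deposition_fraction, 99.9, tolerance = 0.01)
  # deposition fraction curve is monotone
  expect_true(all(diff(res$series$deposited_frac) > -1e-12))
})

test_that("per-step mass budget closes to round-off with flow and markers", {
  g <- grid_spec(nx = 12, ny = 4, nz = 12)
  lat <- build_lattice(n_cilia = 4, wavelength_um = m_to_um(g$Lx))
  res <- run_transport(g, "SAL", flow = NULL, lattice = lat,
                       kappa_att = 0.05, t_end = 0.02,
                       deposition_area_um2 = 55^2)
  expect_lt(res$mass_budget_drift, 1e-8)
  expect_gt(res$attached, 0)
})
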