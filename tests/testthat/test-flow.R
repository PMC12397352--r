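test_that("quiescent film stays quiescent and boundary conditions hold", {
  fx <- make_fixture("tiny-flow")
  st <- flow_state(fx$grid, giesekus = NULL)
  for (i in 1:5) st <- step_flow(st, dt = 1e-6)
  expect_identical(max(abs(st$u), abs(st$v), abs(st$w)), 0)
  # no-penetration on both walls, exactly
  expect_identical(max(abs(st$w[, , 1])), 0)
  expect_identical(max(abs(st$w[, , dim(st$w)[3]])), 0)
})

test_that("elastic stress is masked out of the PCL and top layer", {
  g <- grid_spec(nx = 6, ny = 4, nz = 12, Lz_um = 17, z_interface_um = 7)
  st <- flow_state(g)
  st$tau[[1]]$xx[] <- 1
  st <- apply_flow_bcs(st)
  zc <- m_to_um(g$zc)
  below <- which(zc < 7)
  expect_identical(max(abs(st$tau[[1]]$xx[, , below])), 0)
  expect_identical(max(abs(st$tau[[1]]$xx[, , g$nz])), 0)
  expect_identical(max(st$tau[[1]]$xx[, , 9]), 1)
})

test_that("oscillating-wall shear flow matches the Stokes-layer solution", {
  nu <- 1e-6; om <- 2 * pi * 10
  k <- sqrt(om / (2 * nu))
  Lz_um <- m_to_um(6 / k)
  g <- grid_spec(nx = 4, ny = 4, nz = 72, Lz_um = Lz_um,
                 z_interface_um = Lz_um / 2)
  st <- flow_state(g, fluid_props(1000, 0.001), giesekus = NULL)
  U0 <- 1e-3
  period <- 2 * pi / om
  dt <- period / 300
  for (n in seq_len(4 * 300)) {
    st <- step_flow(st, dt = dt, wall_u = U0 * cos(om * st$t))
  }
  ana <- U0 * exp(-k * g$zc) * cos(om * st$t - k * g$zc)
  num <- st$u[1, 1, ]
  expect_lt(max(abs(num - ana)) / U0, 0.02)
})

test_that("cilia-driven step leaves a discretely divergence-free field", {
  fx <- make_fixture("single-cilium")
  st <- flow_state(fx$grid, giesekus = NULL)
  dt <- (1 / fx$lattice$frequency) / 600
  for (n in 1:30) {
    mk <- cilia_markers(fx$lattice, st$t, fx$grid$h, fx$grid$Ly / 2)
    st <- step_flow(st, mk, dt, n_forcing_iter = 2)
  }
  u_ref <- max(abs(st$u), abs(st$v), abs(st$w))
  expect_gt(u_ref, 0)
  expect_lt(attr(st, "div_max"), 1e-8 * u_ref / fx$grid$h)
})

test_that("dropping the elastic modes reduces to the Newtonian solver", {
  g <- grid_spec(nx = 8, ny = 4, nz = 10)
  lat <- build_lattice(n_cilia = 2, wavelength_um = m_to_um(g$Lx))
  run <- function(gies) {
    st <- flow_state(g, giesekus = gies)
    dt <- 2e-5
    for (n in 1:20) {
      mk <- cilia_markers(lat, st$t, g$h, g$Ly / 2)
      st <- step_flow(st, mk, dt)
    }
    st
  }
  st_none <- run(NULL)
  st_tiny <- run(giesekus_params(eta_p = rep(1e-12, 5)))
  expect_equal(st_tiny$u, st_none$u, tolerance = 1e-6)
  expect_equal(st_tiny$w, st_none$w, tolerance = 1e-6)
})

test_that("layer averages split the film at the PCL-mucus interface", {
  g <- grid_spec(nx = 4, ny = 2, nz = 17, Lz_um = 17, z_interface_um = 7)
  st <- flow_state(g, giesekus = NULL)
  expect_identical(layer_average_velocity(st, "ASL"), 0)
  # synthetic field: 1 um/s in the PCL cells, 3 um/s in the mucus cells
  st$u[, , ] <- um_to_m(ifelse(m_to_um(g$zc) < 7, 1, 3))[
    rep(1:17, each = 8)] |> array(dim = c(4, 2, 17))
  expect_equal(layer_average_velocity(st, "PCL"), 1, tolerance = 1e-12)
  expect_equal(layer_average_velocity(st, "mucus"), 3, tolerance = 1e-12)
  expect_equal(layer_average_velocity(st, "ASL"), (7 * 1 + 10 * 3) / 17,
               tolerance = 1e-12)
})

test_that("advective CFL violation aborts with a suggested step", {
  g <- grid_spec(nx = 6, ny = 4, nz = 8)
  st <- flow_state(g, giesekus = NULL)
  st$u[] <- 1
  expect_error(step_flow(st, dt = 1), "CFL")
})
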