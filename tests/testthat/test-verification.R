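test_that("exact solution satisfies the initial and boundary data", {
  x <- seq(0, 1, by = 0.05)
  expect_equal(analytic_case_exact(x, 0), exp(-(x - 2)^2 / 8))
  expect_equal(analytic_case_exact(0, 0), exp(-0.5))
  # boundary data of the benchmark at a later time
  t <- 0.4
  expect_equal(analytic_case_exact(0, t),
               sqrt(20 / (20 + t)) * exp(-2 * (5 + 2 * t)^2 / (5 * (t + 20))))
  expect_equal(analytic_case_exact(1, t),
               sqrt(20 / (20 + t)) * exp(-(5 + 4 * t)^2 / (10 * (t + 20))))
})

test_that("transport kernel converges at second order on the benchmark", {
  e1 <- solve_analytic_case(n_cells = 64, t_end = 0.4)$max_rel_error
  e2 <- solve_analytic_case(n_cells = 128, t_end = 0.4)$max_rel_error
  e3 <- solve_analytic_case(n_cells = 256, t_end = 0.4)$max_rel_error
  expect_lt(e2, e1); expect_lt(e3, e2)
  expect_equal(log2(e1 / e2), 2, tolerance = 0.35)
  expect_equal(log2(e2 / e3), 2, tolerance = 0.35)
})

test_that("fixture presets build and advertise their properties", {
  for (p in c("tiny-flow", "single-cilium", "tiny-transport", "column-1d")) {
    fx <- make_fixture(p)
    expect_s3_class(fx$grid, "grid_spec")
    expect_true(length(fx$properties) >= 1)
  }
  expect_error(make_fixture("nope"))
  # quiescence property of the tiny-flow preset
  fx <- make_fixture("tiny-flow")
  st <- flow_state(fx$grid, giesekus = NULL)
  st <- step_flow(st, dt = 1e-6)
  expect_identical(max(abs(st$u)), 0)
})

test_that("a single cilium propels the film", {
  fx <- make_fixture("single-cilium")
  st <- flow_state(fx$grid, giesekus = NULL)
  T_c <- 1 / fx$lattice$frequency
  dt <- T_c / 500
  ubar <- 0
  for (n in 1:500) {
    mk <- cilia_markers(fx$lattice, st$t, fx$grid$h, fx$grid$Ly / 2)
    st <- step_flow(st, mk, dt, n_forcing_iter = 2)
    ubar <- ubar + layer_average_velocity(st, "ASL") / 500
  }
  expect_gt(abs(ubar), 1e-4)  # um/s; nonzero cycle-averaged transport
})
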