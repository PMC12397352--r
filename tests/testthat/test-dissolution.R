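test_that("Noyes-Whitney rate matches direct arithmetic and limits", {
  sal <- drug_spec("SAL")
  p <- particle_state(sal, diameter_um = 5)
  # dm/dt = -4 pi r D Cs at zero bulk concentration
  expect_equal(dissolution_rate(p, Cb = 0),
               -4 * pi * 2.5e-6 * 4.6e-10 * 263, tolerance = 1e-12)
  # equilibrium: no driving force at saturation
  expect_identical(dissolution_rate(p, Cb = sal$Cs), 0)
  # fully dissolved particle has zero rate
  p0 <- p; p0$r <- 0
  expect_identical(dissolution_rate(p0, Cb = 0), 0)
  # supersaturated bulk flips the sign and warns
  expect_warning(rate <- dissolution_rate(p, Cb = 2 * sal$Cs),
                 "re-precipitation")
  expect_gt(rate, 0)
})

test_that("radius ODE integration matches the closed form and deSolve", {
  for (nm in c("SAL", "TIO", "RIF")) {
    d <- drug_spec(nm)
    cf <- dissolution_closed_form(d, 5)
    expect_equal(cf$t_d, d$density * (2.5e-6)^2 / (2 * d$D * d$Cs))
    res <- dissolve_particle(d, dt = cf$t_d / 500)
    expect_equal(attr(res, "t_d"), cf$t_d, tolerance = 1e-10)
    expect_equal(max(res$t), cf$t_d, tolerance = 3 / 500)
    # dissolved fraction curve: 1 - (1 - t/t_d)^(3/2)
    mid <- which.min(abs(res$t - cf$t_d / 2))
    expect_equal(res$fraction[mid],
                 1 - (1 - res$t[mid] / cf$t_d)^1.5, tolerance = 1e-6)
  }
  skip_if_not_installed("deSolve")
  d <- drug_spec("TIO")
  ode_fn <- function(t, y, parms) {
    r <- max(y[1], 0)
    list(-d$D * d$Cs / (d$density * max(r, 1e-12)))
  }
  t_probe <- seq(0, 0.2, length.out = 51)
  sol <- deSolve::ode(y = c(r = 2.5e-6), times = t_probe, func = ode_fn,
                      parms = NULL, rtol = 1e-10, atol = 1e-14)
  p <- particle_state(d)
  for (i in 2:length(t_probe)) {
    p <- advance_particle(p, 0, dt = diff(t_probe)[1])
  }
  expect_equal(p$r, unname(sol[nrow(sol), "r"]), tolerance = 1e-6)
})

test_that("particle mass ledger is conserved and lands exactly on r = 0", {
  d <- drug_spec("SAL")
  p <- particle_state(d)
  dt <- 1e-3
  while (p$r > 0) {
    p <- advance_particle(p, Cb = 0, dt = dt)
    expect_equal(p$mass + p$dissolved, p$m0, tolerance = 1e-12)
  }
  expect_identical(p$r, 0)
  expect_equal(p$dissolved, p$m0, tolerance = 1e-12)
})

test_that("dissolution time scales inversely with solubility", {
  base <- drug_spec("TIO")
  for (fac in c(0.5, 2, 4)) {
    mod <- drug_spec("TIO", solubility_mg_ml = base$solubility_mg_ml * fac)
    expect_equal(dissolution_closed_form(mod)$t_d,
                 dissolution_closed_form(base)$t_d / fac,
                 tolerance = 1e-12)
  }
})

test_that("coupled-column dissolution is slower than the free-bulk bound", {
  d <- drug_spec("TIO")
  res <- dissolve_in_column(d, nz = 24)
  expect_gt(attr(res, "t_d"), dissolution_closed_form(d)$t_d)
  expect_lt(attr(res, "mass_budget_rel_err"), 1e-10)
  expect_true(all(res$Cb >= 0), info = "bulk concentration stays nonnegative")
  expect_lt(max(res$Cb), d$Cs)
})

test_that("surface flux conversion is linear in rate and area", {
  expect_identical(surface_flux(0, 1e-9), 0)
  expect_equal(surface_flux(4e-12, 2e-9), 2e-3)
  expect_equal(surface_flux(4e-12, 4e-9), 1e-3)
  expect_error(surface_flux(1, 0))
})
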