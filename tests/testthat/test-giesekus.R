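test_that("stress relaxes exponentially at rest for alpha = 0", {
  dims <- c(1, 1, 1)
  zero <- array(0, dims)
  L0 <- rep(list(rep(list(zero), 3)), 3)
  tau <- mucosim:::tensor_zero(dims)
  tau$xx[] <- 2; tau$xz[] <- 0.7
  lam <- 0.3; dt <- lam / 5000
  for (i in 1:5000) {
    tau <- giesekus_mode_step(tau, L0, dt, lambda = lam, eta_p = 0.5,
                              alpha = 0)
  }
  # one relaxation time elapsed: decay to exp(-1)
  expect_equal(tau$xx[1], 2 * exp(-1), tolerance = 1e-3)
  expect_equal(tau$xz[1], 0.7 * exp(-1), tolerance = 1e-3)
  # symmetric components that started at zero stay zero
  expect_identical(max(abs(tau$yy), abs(tau$yz)), 0)
})

test_that("upper-convected Maxwell steady shear matches the closed form", {
  for (gd in c(2, 10)) {
    ss <- giesekus_steady_shear(gd, lambda = 0.2, eta_p = 0.5, alpha = 0)
    expect_equal(unname(ss["xz"]), 0.5 * gd, tolerance = 1e-6)
    expect_equal(unname(ss["xx"]), 2 * 0.5 * 0.2 * gd^2, tolerance = 1e-6)
    expect_equal(unname(ss["zz"]), 0, tolerance = 1e-8)
  }
})

test_that("nonlinear modes match an independent algebraic root-finder", {
  # the three shear-thinning modes of the bundled mucus fit
  modes <- list(c(0.466, 0.2493, 0.5), c(3.129, 1.4215, 0.5),
                c(0.0821, 0.062, 0.3))
  for (m in modes) {
    for (gd in c(1, 20)) {
      marched <- giesekus_steady_shear(gd, m[1], m[2], m[3])
      oracle <- steady_shear_oracle(gd, m[1], m[2], m[3])
      expect_equal(unname(marched["xz"]), unname(oracle["xz"]),
                   tolerance = 1e-3)
      expect_equal(unname(marched["xx"]), unname(oracle["xx"]),
                   tolerance = 1e-3)
    }
  }
})

test_that("shear thinning: effective viscosity falls below the Maxwell one", {
  gd <- 50
  nl <- giesekus_steady_shear(gd, 0.466, 0.2493, 0.5)
  expect_lt(nl["xz"] / gd, 0.2493)
})

test_that("mode step preserves symmetry storage and rejects blow-up", {
  dims <- c(2, 2, 2)
  zero <- array(0, dims)
  gd <- array(5, dims)
  L <- list(list(zero, zero, gd), list(zero, zero, zero),
            list(zero, zero, zero))
  tau <- mucosim:::tensor_zero(dims)
  tau <- giesekus_mode_step(tau, L, 1e-3, 0.1, 0.3, 0.5)
  expect_named(tau, c("xx", "yy", "zz", "xy", "xz", "yz"))
  tau_bad <- mucosim:::tensor_zero(dims)
  tau_bad$xx[] <- Inf
  expect_error(giesekus_mode_step(tau_bad, L, 1e-3, 0.1, 0.3, 0.5),
               "diverged")
})

test_that("parameter container validates the mobility range", {
  gp <- giesekus_params()
  expect_equal(gp$n_modes, 5)
  expect_error(giesekus_params(alpha = c(0.2, 0.3, 0.5, 0.5, 1.5)))
  expect_error(giesekus_params(lambda = c(-1, 1, 1, 1, 1)))
})
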