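test_that("marker counts reproduce the grid-matched mesh family", {
  # reference meshes: h = 17 um / nz; counts N_ax x N_ang per cilium
  cases <- list(M1 = c(131, 39, 4), M2 = c(175, 51, 5),
                M3 = c(219, 64, 6), M4 = c(262, 77, 7))
  straight <- function(s) cbind(0 * s, 0 * s, 5e-6 * s)
  for (nm in names(cases)) {
    h <- 17e-6 / cases[[nm]][1]
    mk <- suppressWarnings(
      mesh_cilium_surface(straight, 5e-6, 0.15e-6, h))
    expect_equal(mk$N_ax, cases[[nm]][2], info = nm)
    expect_equal(mk$N_ang, cases[[nm]][3], info = nm)
  }
})

test_that("a straight cilium meshes as a cylinder with a one-cell shell", {
  L <- 5e-6; d <- 0.3e-6; h <- 0.2e-6
  straight <- function(s) cbind(0 * s, 0 * s, L * s)
  mk <- mesh_cilium_surface(straight, L, d, h)
  rad <- sqrt(mk$X[, 1]^2 + mk$X[, 2]^2)
  expect_equal(rad, rep(d / 2, nrow(mk$X)), tolerance = 1e-9)
  # total shell volume = pi * d * L * h
  expect_equal(sum(mk$dV), pi * d * L * h, tolerance = 1e-12)
  # under-resolved marker spacing warns
  expect_warning(mesh_cilium_surface(straight, L, d, h, N_ax = 2),
                 "under-resolved")
})

test_that("lattice markers stay in the film and track the beat velocity", {
  lat <- build_lattice(n_cilia = 4, wavelength_um = 8)
  h <- 0.5e-6
  mk <- cilia_markers(lat, t = 0.013, dx = h, y0 = 2e-6)
  expect_s3_class(mk, "lagrangian_markers")
  expect_equal(nrow(mk$X), 4 * mk$N_ax * mk$N_ang)
  expect_true(all(mk$X[, 3] > 0))
  expect_true(all(mk$X[, 3] <= 5.2e-6))  # within cilium length + radius
  # each cilium's markers carry its own phase: distinct velocities
  v1 <- mk$U[mk$cilium == 1, 1]
  v3 <- mk$U[mk$cilium == 3, 1]
  expect_gt(max(abs(v1 - v3)), 0)
  # CSV export round-trips
  tmp <- tempfile(fileext = ".csv")
  write_markers_csv(mk, tmp)
  df <- read.csv(tmp)
  expect_equal(nrow(df), nrow(mk$X))
  expect_equal(df$z, mk$X[, 3])
})

test_that("marker resolution refines with the grid", {
  lat <- build_lattice(n_cilia = 1)
  mk_coarse <- cilia_markers(lat, 0, dx = 17e-6 / 131)
  mk_fine <- cilia_markers(lat, 0, dx = 17e-6 / 262)
  expect_equal(mk_fine$N_ax / mk_coarse$N_ax, 2, tolerance = 0.05)
})
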