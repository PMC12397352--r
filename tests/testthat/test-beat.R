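bm <- beat_model()

test_that("beat centerline is anchored, periodic and inextensible", {
  # base at the origin for any phase
  for (ph in c(0, 0.31, 0.77)) {
    expect_equal(unname(beat_shape(bm, ph, 0)[1, ]), c(0, 0, 0))
  }
  # exact 1-periodicity in phase
  s <- c(0.2, 0.6, 1)
  expect_equal(beat_shape(bm, 0.37, s), beat_shape(bm, 1.37, s),
               tolerance = 1e-12)
  expect_equal(beat_velocity(bm, 0.81, s), beat_velocity(bm, -0.19, s),
               tolerance = 1e-12)
  # arclength equals the cilium length within 2% at all 13 reference states
  arcs <- vapply((0:12) / 13, function(p) beat_arclength(bm, p), numeric(1))
  expect_true(all(abs(arcs / bm$L - 1) < 0.02))
  # the centerline never dips below the epithelial wall
  zmin <- min(vapply((0:199) / 200, function(p)
    min(beat_shape(bm, p, seq(0, 1, by = 0.05))[, 3]), numeric(1)))
  expect_gte(zmin, -1e-9 * bm$L)
})

test_that("beat velocity is the phase derivative of the shape", {
  dp <- 1e-5
  for (probe in list(c(0.1, 0.5), c(0.42, 1), c(0.9, 0.25))) {
    fd <- (beat_shape(bm, probe[1] + dp, probe[2]) -
             beat_shape(bm, probe[1] - dp, probe[2])) / (2 * dp) * bm$f
    an <- beat_velocity(bm, probe[1], probe[2])
    expect_equal(an, fd, tolerance = 1e-6)
  }
  # closed periodic orbit: cycle-averaged velocity vanishes at every station
  ph <- (0:399) / 400
  for (s in c(0.3, 1)) {
    vbar <- rowMeans(vapply(ph, function(p) beat_velocity(bm, p, s)[1, ],
                            numeric(3)))
    expect_lt(max(abs(vbar)), 1e-12 * bm$L * bm$f)
  }
})

test_that("effective stroke is faster than the recovery stroke", {
  ph <- (0:199) / 200
  spd <- vapply(ph, function(p) sqrt(sum(beat_velocity(bm, p, 1)^2)),
                numeric(1))
  eff <- ph >= bm$effective_window[1] & ph < bm$effective_window[2]
  expect_gt(mean(spd[eff]), mean(spd[!eff]))
})

test_that("lattice phases are uniform and antiplectic defaults hold", {
  lat <- build_lattice(n_cilia = 100)
  expect_equal(lat$n, 100)
  expect_equal(diff(lat$phase), rep(0.01, 99))
  expect_equal(m_to_um(lat$spacing), 55 / 100)
  expect_equal(m_to_um(lat$Lx), 55)
  lat1 <- build_lattice(n_cilia = 1)
  expect_identical(lat1$phase, 0)
  lat13 <- build_lattice(n_cilia = 13)
  expect_equal(lat13$phase, (0:12) / 13)
  expect_error(build_lattice(n_cilia = 4, spacing_um = -1), "spacing")
})
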