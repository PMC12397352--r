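test_that("deposition times from a synthetic constant-rate ledger", {
  t <- seq(0, 2, by = 0.01)
  dep <- pmin(t, 1)          # constant rate until complete at t = 1
  dt_out <- deposition_times(t, dep)
  expect_equal(dt_out$complete_deposition_time, 1, tolerance = 0.011)
  # rate plateau: argmax of the instantaneous rate is within the ramp
  expect_lte(dt_out$max_deposition_time, 1)
  # never-complete series warns and returns NA
  expect_warning(out <- deposition_times(t, dep * 0.5), "threshold")
  expect_true(is.na(out$complete_deposition_time))
  # a deposition + attachment split still completes
  out2 <- deposition_times(t, dep * 0.6, dep * 0.4)
  expect_equal(out2$complete_deposition_time, 1, tolerance = 0.011)
  expect_error(deposition_times(t, rev(dep)), "non-decreasing")
})

test_that("fraction curves close to 100 percent", {
  t <- seq(0, 1, by = 0.1)
  m0 <- 2e-13
  led <- data.frame(
    t = t,
    dissolved = m0 * pmin(t, 1),
    deposited = m0 * 0.6 * pmin(t, 1),
    attached = m0 * 0.1 * pmin(t, 1),
    in_domain = m0 * 0.3 * pmin(t, 1))
  fr <- fractions(led, m0)
  expect_true(all(abs(fr$closure_error) < 1e-10))
  expect_equal(fr$dissolved[11], 100)
  expect_error(fractions(led, 0), "positive")
})

test_that("episode metrics summarise ledgers consistently", {
  g <- grid_spec(nx = 2, ny = 2, nz = 24)
  res <- run_transport(g, "SAL", deposition_area_um2 = 55^2)
  m <- transport_metrics(res)
  expect_equal(m$total_deposition_fraction, 99.9, tolerance = 0.01)
  expect_gte(m$complete_deposition_time, m$max_deposition_time)
  expect_gte(m$complete_deposition_time, m$complete_dissolution_time)
  expect_equal(m$kappa_att, 0)
  # closure at every sample
  s <- res$series
  closure <- s$deposited_frac + s$attached_frac + s$in_domain_frac +
    (1 - s$dissolved_frac)
  expect_true(all(abs(closure - 1) < 1e-4))
})
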