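test_that("regularized delta kernel: branch values and partition of unity", {
  expect_equal(ibm_phi(0), 2 / 3)
  expect_equal(ibm_phi(1.5), 0)
  expect_equal(ibm_phi(-1.5), 0)
  expect_identical(ibm_phi(2.3), 0)
  # continuity at the branch points
  expect_equal(ibm_phi(0.5 - 1e-10), ibm_phi(0.5 + 1e-10), tolerance = 1e-6)
  expect_true(all(ibm_phi(seq(-2, 2, by = 0.01)) >= 0))
  set.seed(11)
  r <- runif(1000, -4, 4)
  pou <- vapply(r, function(x) sum(ibm_phi(x - (-6:6))), numeric(1))
  expect_equal(pou, rep(1, 1000), tolerance = 1e-12)
})

h <- 0.1
dims <- c(16, 8, 12)
set.seed(42)
X <- cbind(runif(40, 0, 1.6), runif(40, 0, 0.8), runif(40, 0.25, 0.95))
st <- ibm_stencil(X, c(h / 2, h / 2, h / 2), h, dims, zfold = "error")

test_that("interpolation reproduces constant and linear fields", {
  expect_equal(ibm_interpolate(array(7.3, dims), st), rep(7.3, 40),
               tolerance = 1e-12)
  xc <- (seq_len(dims[1]) - 0.5) * h
  flin <- array(rep(3 * xc, times = dims[2] * dims[3]), dims)
  keep <- X[, 1] > 0.2 & X[, 1] < 1.4   # clear of the periodic seam
  sti <- ibm_stencil(X[keep, , drop = FALSE], c(h / 2, h / 2, h / 2), h,
                     dims, zfold = "error")
  expect_equal(ibm_interpolate(flin, sti), 3 * X[keep, 1],
               tolerance = 1e-10)
})

test_that("spreading conserves the total source exactly", {
  set.seed(7)
  Q <- rnorm(40); dV <- runif(40, 0.5, 1.5) * h^3
  q <- ibm_spread(Q, dV, st)
  expect_equal(sum(q) * h^3, sum(Q * dV), tolerance = 1e-12)
  expect_identical(ibm_spread(rep(0, 40), dV, st), array(0, dims))
  # near-wall even fold still conserves
  Xw <- cbind(runif(15, 0, 1.6), runif(15, 0, 0.8), runif(15, 0, 0.08))
  stw <- ibm_stencil(Xw, c(h / 2, h / 2, h / 2), h, dims, zfold = "even")
  qw <- ibm_spread(rep(1, 15), rep(h^3, 15), stw)
  expect_equal(sum(qw) * h^3, 15 * h^3, tolerance = 1e-12)
})

test_that("spread and interpolate are discrete adjoints", {
  set.seed(3)
  Q <- rnorm(40); dV <- runif(40, 0.5, 1.5) * h^3
  f <- array(rnorm(prod(dims)), dims)
  lhs <- sum(ibm_spread(Q, dV, st) * f) * h^3
  rhs <- sum(Q * dV * ibm_interpolate(f, st))
  expect_equal(lhs, rhs, tolerance = 1e-12 * abs(lhs))
})

test_that("stencil crossing a wall errors under the strict policy", {
  Xbad <- matrix(c(0.5, 0.4, 0.05), 1, 3)
  expect_error(ibm_stencil(Xbad, c(h / 2, h / 2, h / 2), h, dims,
                           zfold = "error"), "1.5 cells")
})

test_that("periodic translation by one cell shifts the spread field", {
  Q <- rep(1, 40); dV <- rep(h^3, 40)
  q0 <- ibm_spread(Q, dV, st)
  Xs <- X; Xs[, 1] <- (Xs[, 1] + h) %% (dims[1] * h)
  sts <- ibm_stencil(Xs, c(h / 2, h / 2, h / 2), h, dims, zfold = "error")
  q1 <- ibm_spread(Q, dV, sts)
  expect_equal(q1, q0[c(dims[1], 1:(dims[1] - 1)), , ], tolerance = 1e-12)
})

test_that("sparse operator agrees with the direct stencil path", {
  dV <- runif(40, 0.5, 1.5) * h^3
  op <- ibm_operator(st, dV)
  f <- array(rnorm(prod(dims)), dims)
  expect_equal(ibm_interpolate(f, op), ibm_interpolate(f, st),
               tolerance = 1e-12)
  Q <- rnorm(40)
  expect_equal(ibm_spread(Q, dV, op), ibm_spread(Q, dV, st),
               tolerance = 1e-12)
  expect_true(all(op$G > 0))
})
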