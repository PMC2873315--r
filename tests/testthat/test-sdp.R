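# first-order conic solver

test_that("largest-eigenvalue SDP matches the dense eigensolver", {
  set.seed(1)
  k <- 8
  M <- matrix(rnorm(k * k), k); M <- (M + t(M)) / 2
  nsv <- discrimODE:::svec_dim(k)
  A <- cbind(-discrimODE:::svec(diag(k)), diag(nsv))
  b <- -discrimODE:::svec(M)
  cvec <- c(1, rep(0, nsv))
  res <- sdp_solve(A, b, cvec, cone = list(free = 1, nonneg = 0, psd = k),
                   tol = 1e-8)
  expect_equal(res$status, "optimal")
  expect_equal(res$x[1], max(eigen(M, symmetric = TRUE)$values),
               tolerance = 1e-7)
  # the equality dual is (minus) the rank-one moment matrix of the top
  # eigenvector, which the extraction machinery relies on
  v1 <- eigen(M, symmetric = TRUE)$vectors[, 1]
  expect_lt(max(abs(res$y + discrimODE:::svec(tcrossprod(v1)))), 1e-6)
})

test_that("linear programmes and certificates of infeasibility/unboundedness", {
  # min -x1 - x2 s.t. x1 + x2 + s = 1, x >= 0
  res <- sdp_solve(matrix(c(1, 1, 1), 1), 1, c(-1, -1, 0),
                   cone = list(free = 0, nonneg = 3, psd = integer(0)),
                   tol = 1e-8)
  expect_equal(res$objective, -1, tolerance = 1e-6)
  # x >= 0 with x = -1 is infeasible
  res <- sdp_solve(matrix(1, 1, 1), -1, 0,
                   cone = list(free = 0, nonneg = 1, psd = integer(0)))
  expect_equal(res$status, "infeasible")
  # min -x1 with x1 = x2, x >= 0 is unbounded
  res <- sdp_solve(matrix(c(1, -1), 1), 0, c(-1, 0),
                   cone = list(free = 0, nonneg = 2, psd = integer(0)))
  expect_equal(res$status, "unbounded")
})

test_that("svec round-trips and preserves inner products", {
  set.seed(3)
  for (k in c(2, 5)) {
    M <- matrix(rnorm(k * k), k); M <- M + t(M)
    N <- matrix(rnorm(k * k), k); N <- N + t(N)
    expect_equal(discrimODE:::unsvec(discrimODE:::svec(M), k), M)
    expect_equal(sum(discrimODE:::svec(M) * discrimODE:::svec(N)),
                 sum(M * N))
  }
})
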