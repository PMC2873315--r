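# SOS membership, storage construction, gain bounds and extraction on small
# hand-checkable systems

test_that("a perfect square is certified SOS with tiny identity residual", {
  r <- sos_check("x^4 - 2*x^2 + 1", vars = "x")
  expect_true(r$is_sos)
  expect_lt(r$residual, 1e-6)
  ev <- eigen(r$Q, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-7)
})

test_that("the Motzkin polynomial is nonnegative but not SOS", {
  r <- sos_check("x^4*y^2 + x^2*y^4 - 3*x^2*y^2 + 1", vars = c("x", "y"))
  expect_false(r$is_sos)
})

test_that("the Lyapunov identity of a stable linear system is SOS with zero slack", {
  set.seed(21)
  A <- matrix(rnorm(4), 2); A <- A - (max(Re(eigen(A)$values)) + 0.5) * diag(2)
  C <- matrix(rnorm(2), 1)
  P <- discrimODE:::lyapunov_solve(A, crossprod(C))
  vars <- c("x1", "x2")
  xp <- lapply(vars, discrimODE:::poly_var, vars = vars)
  S <- discrimODE:::poly_zero(vars)
  for (i in 1:2) for (j in 1:2)
    S <- discrimODE:::poly_add(S, discrimODE:::poly_scale(
      discrimODE:::poly_mul(xp[[i]], xp[[j]]), P[i, j]))
  E <- discrimODE:::poly_zero(vars)
  for (k in 1:2) {
    fk <- discrimODE:::poly_add(discrimODE:::poly_scale(xp[[1]], A[k, 1]),
                                discrimODE:::poly_scale(xp[[2]], A[k, 2]))
    E <- discrimODE:::poly_sub(E, discrimODE:::poly_mul(
      discrimODE:::poly_diff(S, vars[k]), fk))
  }
  h <- discrimODE:::poly_add(discrimODE:::poly_scale(xp[[1]], C[1, 1]),
                             discrimODE:::poly_scale(xp[[2]], C[1, 2]))
  E <- discrimODE:::poly_sub(E, discrimODE:::poly_mul(h, h))
  # -grad(x'Px) . Ax - x'C'Cx is identically zero, hence trivially SOS
  expect_lt(max(abs(E$coef), 0), 1e-10)
})

test_that("storage for linear scalar rivals recovers the observability gramian", {
  ds <- scalar_pair_ds()
  cert <- storage_for_ic_design(ds, alpha = 1, deg_S = 2)
  P <- observability_gramian(linearize(ds))$P
  Sq <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    e <- rep(0, 2); e[i] <- e[i] + 1; e[j] <- e[j] + 1
    Sq[i, j] <- discrimODE:::poly_coef_of(cert$S, e) / (if (i == j) 1 else 2)
  }
  expect_lt(max(abs(Sq - P)) / max(abs(P)), 0.05)
  expect_true(cert$verification$ok)
})

test_that("storage construction is infeasible for unstable drift", {
  ds_bad <- fake_scalar_ds(a = +1)     # x' = +x has no storage function
  expect_error(storage_for_ic_design(ds_bad, alpha = 1, deg_S = 2),
               class = "discrim_infeasible_error")
})

test_that("scalar gain bound equals the H-infinity norm of the linear pair", {
  ds <- scalar_pair_ds()
  g <- l2_gain_bound(ds, alpha = 1, deg_S = 2, tol = 1e-7)
  lingain <- frequency_peak(linearize(ds))$gain
  expect_equal(g$gain, lingain, tolerance = 2e-3)
  expect_gte(g$gain, lingain - 2e-4)
})

test_that("certified gain never improves when the storage degree rises", {
  ds <- scalar_pair_ds()
  g2 <- l2_gain_bound(ds, alpha = 1, deg_S = 2, tol = 1e-7)
  g4 <- l2_gain_bound(ds, alpha = 1, deg_S = 4, tol = 1e-7)
  expect_lte(g4$gain, g2$gain + 1e-3)
})

test_that("level-set extraction of a quadratic form returns its top eigenvector", {
  # build a certificate by hand with a known quadratic storage
  vars <- c("x_m1", "y_m1", "x_m2", "y_m2")
  M <- diag(c(3, 1))    # common restriction has R = 4 * M-ish structure
  S <- discrimODE:::poly_zero(vars)
  for (i in 1:2) for (j in 1:2) {
    for (a in c(0, 2)) for (b in c(0, 2)) {
      e <- rep(0, 4); e[i + a] <- e[i + a] + 1; e[j + b] <- e[j + b] + 1
      S <- discrimODE:::poly_add(S, discrimODE:::new_polyform(vars, matrix(e, 1), M[i, j] / 4))
    }
  }
  cert <- structure(list(kind = "ic", S = S, alpha = 1, n1 = 2, n2 = 2,
                         vars = vars), class = "storage_certificate")
  ext <- extract_optimal_ic(cert, beta = 1)
  expect_equal(abs(ext$direction), c(1, 0), tolerance = 1e-3)
  expect_equal(ext$energy_bound, 3, tolerance = 1e-3)
  # beta = 0 is the trivial design
  ext0 <- extract_optimal_ic(cert, beta = 0)
  expect_equal(ext0$energy_bound, 0)
  expect_equal(ext0$xhat, c(0, 0))
})
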