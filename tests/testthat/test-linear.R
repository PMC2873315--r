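# linearization, gramian design, frequency peaks

test_that("linearizing linear rivals returns their own matrices", {
  ds <- scalar_pair_ds()
  lin <- linearize(ds)
  expect_equal(lin$A, diag(c(-1, -2)))
  expect_equal(unname(lin$B), matrix(c(1, 1), 2, 1))
  expect_equal(unname(lin$C), matrix(c(1, -1), 1, 2))
})

test_that("case-study Jacobian blocks carry the activator decay rate", {
  lin <- dicty_lin()
  # the A-equation is dA/dt = ka S - kma A in both rivals: diagonal -2
  expect_equal(lin$A[1, 1], -2)
  expect_equal(lin$A[4, 4], -2)
  expect_true(all(Re(lin$eigenvalues) < 0))
})

test_that("scalar observability gramian has its closed form 1/(2a)", {
  m <- ode_model("x", drift = "-x", output_map = "x")
  s <- compute_steady_state(m, guess = 0.3)
  ds <- concatenate_models(s, s)
  # identical rivals: C = 0, so use the Lyapunov solver directly
  P <- discrimODE:::lyapunov_solve(matrix(-1, 1, 1), matrix(1, 1, 1))
  expect_equal(P[1, 1], 0.5)
})

test_that("gramian energy identity holds against simulation of the linear system", {
  gd <- observability_gramian(dicty_lin())
  lds <- dicty_linear_ds()
  set.seed(7)
  for (i in 1:20) {
    x0 <- rnorm(6, sd = 0.3)
    tr <- simulate_difference_system(lds, ic = x0, rtol = 1e-10, dt = 1)
    pred <- as.numeric(t(x0) %*% gd$P %*% x0)
    expect_equal(tr$l2_norm^2, pred, tolerance = 1e-3)
  }
  expect_true(all(eigen(gd$P, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
})

test_that("optimal common direction is the activator axis, matching brute force on v'Rv", {
  gd <- observability_gramian(dicty_lin())
  od <- optimal_common_initial_direction(gd)
  expect_equal(od$direction, c(1, 0, 0), tolerance = 1e-6)
  # brute-force oracle over a Fibonacci sphere grid
  V <- discrimODE:::sphere_grid(3, 2000)
  vals <- rowSums((V %*% gd$R) * V)
  vbest <- V[which.max(vals), ]
  expect_gt(abs(sum(vbest * od$direction)), 0.999)
  expect_equal(max(vals), od$energy_bound, tolerance = 1e-3)
})

test_that("identical rivals give a degenerate design error", {
  m <- dictyostelium_models()$model1
  ds <- difference_system(m, m, guess1 = dicty_guess, guess2 = dicty_guess)
  lin <- linearize(ds)
  gd <- observability_gramian(lin)
  expect_error(optimal_common_initial_direction(gd),
               class = "discrim_degenerate_error")
})

test_that("frequency peaks match the printed critical frequencies and gains", {
  lin <- dicty_lin()
  fp <- frequency_peak(lin)
  expect_equal(fp$gain, 0.4766, tolerance = 2e-4)
  expect_equal(fp$omega0, 0.4470, tolerance = 2e-4)
  fpr <- frequency_peak(lin, output = "Rstar")
  expect_equal(fpr$gain, 0.02038, tolerance = 2e-4)
  expect_equal(fpr$omega0, 0.3853, tolerance = 2e-4)
  fpi <- frequency_peak(lin, output = "I")
  expect_equal(fpi$omega0, 0.4472, tolerance = 2e-4)
})

test_that("a first-order lag peaks at the low-frequency end without a flat flag", {
  lin <- structure(list(A = matrix(-1, 1, 1), B = matrix(1, 1, 1),
                        C = matrix(1, 1, 1), q = 1, l = 1,
                        output_names = "y"), class = "lin_diff")
  fp <- frequency_peak(lin, grid_range = c(1e-2, 1e2), grid_n = 400)
  expect_false(fp$flat)
  expect_equal(fp$omega0, 1e-2, tolerance = 1e-6)
  expect_equal(fp$gain, 1 / sqrt(1 + fp$omega0^2), tolerance = 1e-6)
})

test_that("peak gain is invariant under state-space similarity transforms", {
  lin <- dicty_lin()
  fp <- frequency_peak(lin)
  set.seed(9)
  T <- matrix(rnorm(36), 6); T <- T + 6 * diag(6)
  lin2 <- structure(list(A = T %*% lin$A %*% solve(T), B = T %*% lin$B,
                         C = lin$C %*% solve(T), q = 1, l = 3,
                         output_names = lin$output_names), class = "lin_diff")
  fp2 <- frequency_peak(lin2)
  expect_equal(fp2$gain, fp$gain, tolerance = 1e-6)
  expect_equal(fp2$omega0, fp$omega0, tolerance = 1e-4)
})

test_that("small common perturbations reach the linear energy bound", {
  gd <- observability_gramian(dicty_lin())
  od <- optimal_common_initial_direction(gd)
  ds <- dicty_ds()
  for (delta in c(1e-2, 1e-3)) {
    tr <- simulate_difference_system(ds, common_ic = delta * od$direction,
                                     rtol = 1e-11, atol = 1e-14)
    expect_equal(tr$l2_norm^2 / delta^2, od$energy_bound, tolerance = 0.05)
  }
})

test_that("the damped-cosine stimulus degenerates to a cosine at zero damping", {
  sig0 <- build_near_optimal_input(0.447, damping = 0, T_active = 60)
  sigc <- input_signal("cosine", omega = 0.447, T_active = 60)
  tt <- seq(0, 70, by = 0.37)
  expect_equal(sig0$fun(tt), sigc$fun(tt), tolerance = 1e-10)
  sig <- build_near_optimal_input(0.447, T_active = 60)
  expect_equal(discrimODE:::signal_energy(sig), 1, tolerance = 1e-6)
  expect_true(all(sig$fun(seq(60.01, 100, by = 1)) == 0))
})
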