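# nonlinear simulation, L2 norms, brute-force oracles

test_that("the equilibrium is invariant under zero input", {
  tr <- simulate_difference_system(dicty_ds(), common_ic = rep(0, 3))
  expect_lt(tr$l2_norm, 1e-8)
  expect_true(all(abs(tr$states) < 1e-8))
})

test_that("released perturbations reproduce the printed output-difference norms", {
  ds <- dicty_ds()
  tr1 <- simulate_difference_system(ds, common_ic = rep(0.5774, 3))
  expect_lt(abs(signal_l2_norm(tr1) - 0.420), 0.005)
  tr2 <- simulate_difference_system(ds, common_ic = c(1, 0, 0))
  expect_lt(abs(signal_l2_norm(tr2) - 0.729), 0.005)
  expect_true(all(diff(tr1$energy) >= -1e-12))
  expect_lt(tr1$tail_fraction, 1e-6)
})

test_that("reported norms are converged in the integrator tolerance", {
  ds <- dicty_ds()
  a <- simulate_difference_system(ds, common_ic = c(1, 0, 0),
                                  rtol = 1e-9, atol = 1e-12)$l2_norm
  b <- simulate_difference_system(ds, common_ic = c(1, 0, 0),
                                  rtol = 5e-10, atol = 5e-13)$l2_norm
  expect_lt(abs(a - b), 1e-4)
})

test_that("output energy scales linearly with perturbation size in the linear regime", {
  ds <- dicty_ds()
  v <- c(1, 0, 0)
  n1 <- simulate_difference_system(ds, common_ic = 1e-3 * v,
                                   rtol = 1e-11, atol = 1e-15)$l2_norm
  n2 <- simulate_difference_system(ds, common_ic = 1e-2 * v,
                                   rtol = 1e-11, atol = 1e-15)$l2_norm
  expect_equal(n2 / n1, 10, tolerance = 0.01)
})

test_that("trajectory norms against the gramian oracle on the linear rivals", {
  lds <- dicty_linear_ds()
  gd <- observability_gramian(linearize(lds))
  x0 <- c(0.3, -0.1, 0.2, 0.3, -0.1, 0.2)
  tr <- simulate_difference_system(lds, ic = x0, rtol = 1e-10)
  expect_equal(tr$l2_norm^2, as.numeric(t(x0) %*% gd$P %*% x0),
               tolerance = 1e-3)
})

test_that("non-decaying dynamics are reported, not silently integrated", {
  # a marginal oscillator pair is outside the method's assumptions and the
  # steady-state machinery refuses it upfront
  m <- ode_model(c("x", "y"), drift = c("y", "-x"), output_map = "x")
  expect_error(compute_steady_state(m, guess = c(0.1, 0.1)),
               class = "discrim_stability_error")
})

test_that("brute-force search recovers the activator direction and its value", {
  ds <- dicty_ds()
  br <- brute_force_ic_search(ds, beta = 1, grid_size = 200)
  expect_gt(abs(sum(br$direction * c(1, 0, 0))), 0.995)
  expect_lt(abs(br$value - 0.729), 0.005)
  # degenerate single-point grid is defined
  one <- brute_force_ic_search(ds, beta = 1, grid_size = 1, refine = FALSE)
  expect_equal(length(one$direction), 3)
})

test_that("brute-force direction agrees with the gramian eigenvector on linear rivals", {
  lds <- dicty_linear_ds()
  od <- optimal_common_initial_direction(observability_gramian(linearize(lds)))
  br <- brute_force_ic_search(lds, beta = 0.01, grid_size = 150)
  expect_gt(abs(sum(br$direction * od$direction)), 0.99)
})

test_that("structural brute force with a collapsed box reduces to the plain search", {
  mods <- dictyostelium_models()
  box <- list(kr = c(1, 1), RT = c(23 / 30, 23 / 30))
  st <- brute_force_structural_search(mods$model1, mods$model2, box,
                                      beta = 1, grid_size = 60)
  br <- brute_force_ic_search(dicty_ds(), beta = 1, grid_size = 60)
  expect_equal(st$value, br$value, tolerance = 1e-4)
  expect_gt(abs(sum(st$direction * br$direction)), 0.999)
})
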