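# SOS design machinery on the chemotaxis case study

test_that("the case-study storage function approximates the gramian and is certified", {
  cert <- dicty_storage()
  P <- observability_gramian(dicty_lin())$P
  Sq <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    e <- rep(0, 6); e[i] <- e[i] + 1; e[j] <- e[j] + 1
    Sq[i, j] <- discrimODE:::poly_coef_of(cert$S, e) / (if (i == j) 1 else 2)
  }
  # trace-minimal storage sits just above the gramian
  expect_lt(max(abs(Sq - P)) / max(abs(P)), 0.05)
  expect_lt(cert$verification$residual, 1e-5)
  expect_gt(min(cert$verification$min_eig), -1e-5)
})

test_that("storage level-set extraction picks the activator direction", {
  ext <- extract_optimal_ic(dicty_storage(), beta = 1)
  expect_gt(abs(sum(ext$direction * c(1, 0, 0))), 0.999)
  expect_equal(ext$route, "dual_moment")
  expect_lt(ext$rank_ratio, 1e-3)
})

test_that("the storage bound dominates simulated output energy inside the level set", {
  cert <- dicty_storage()
  ds <- dicty_ds()
  # certified level: largest sublevel set of S inside |x_i| <= alpha; sample
  # from small common and non-common perturbations well inside the region
  eval_S <- function(x) discrimODE:::poly_eval(cert$S, stats::setNames(x, cert$vars))
  set.seed(31)
  worst <- 0
  for (i in 1:25) {
    x0 <- runif(6, -1, 1)
    x0 <- x0 / max(sqrt(sum(x0[1:3]^2)), sqrt(sum(x0[4:6]^2))) *
      runif(1, 0.2, 0.95) * cert$alpha
    tr <- simulate_difference_system(ds, ic = x0, rtol = 1e-10)
    worst <- max(worst, tr$l2_norm^2 - eval_S(x0))
  }
  expect_lt(worst, 1e-6)
})

test_that("the SOS gain bound sits just above the linear peak gain", {
  g <- dicty_gain()
  lingain <- frequency_peak(dicty_lin())$gain
  expect_equal(g$gain, 0.477, tolerance = 0.01)
  expect_gte(g$gain, lingain - 5e-4)
})

test_that("simulated input-output gains never exceed the certified bound", {
  g <- dicty_gain()
  ds <- dicty_ds()
  fp <- frequency_peak(dicty_lin())
  sigs <- list(
    input_signal("sine", omega = fp$omega0, T_active = 60),
    input_signal("cosine", omega = fp$omega0, T_active = 60),
    input_signal("sine", omega = 0.3853, T_active = 60),
    input_signal("square", omega = fp$omega0, T_active = 60),
    input_signal("sinc", omega = fp$omega0, T_active = 60),
    input_signal("constant", T_active = 60),
    input_signal("exp_mod_sine", omega = fp$omega0, T_active = 60),
    input_signal("sine", omega = 1.2, T_active = 60),
    input_signal("square", omega = 0.2, T_active = 30),
    input_signal("constant", T_active = 5)
  )
  for (sig in sigs) {
    tr <- simulate_difference_system(ds, input = sig, rtol = 1e-8)
    expect_lte(signal_l2_norm(tr), g$gain + 1e-3)
  }
})
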