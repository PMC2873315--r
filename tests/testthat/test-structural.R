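# structural (parameter) design: symbolic shift, denominator clearing,
# brute-force search

test_that("symbolic steady state matches the numeric solver across the box", {
  mods <- dictyostelium_models("structural_design")
  ss <- discrimODE:::symbolic_steady_state(mods$model1, c("kr", "RT"))
  origin <- stats::setNames(rep(0, 3), mods$model1$states)
  for (kr in c(0.5, 1.0, 1.5)) for (RT in c(0.5, 1.75, 3.0)) {
    pp <- c(kr = kr, RT = RT)
    num <- compute_steady_state(mods$model1, guess = dicty_guess, params = pp)
    sym <- vapply(mods$model1$states, function(s)
      discrimODE:::rat_eval(ss[[s]], c(pp, origin)), 0)
    expect_equal(unname(sym), unname(num$x_star), tolerance = 1e-10)
  }
  # activator and inhibitor equilibria are parameter-free; the response
  # regulator carries the rational kr dependence
  expect_true(discrimODE:::rat_is_poly(ss$A))
  expect_false(discrimODE:::rat_is_poly(ss$Rstar))
})

test_that("sequential elimination refuses models outside its structure", {
  # x' = -x^3 + k is not linear in x in its own equation
  m <- ode_model("x", params = c(k = 1), drift = "k - x^3", output_map = "x",
                 param_boxes = list(k = c(0.5, 2)))
  expect_error(discrimODE:::symbolic_steady_state(m, "k"),
               class = "discrim_symbolic_error")
})

test_that("parametric deviation drift vanishes at the origin symbolically", {
  mods <- dictyostelium_models("structural_design")
  d1 <- discrimODE:::symbolic_shifted_drift(mods$model1, c("kr", "RT"))
  for (comp in d1) {
    num0 <- comp$num
    if (length(num0$coef)) {
      xcols <- match(mods$model1$states, num0$vars)
      expect_true(all(rowSums(num0$expo[, xcols, drop = FALSE]) >= 1))
    }
  }
})

test_that("grid search over the box lands on the printed optimum", {
  mods <- dictyostelium_models("structural_design")
  st <- brute_force_structural_search(mods$model1, mods$model2,
                                      param_grid = 3, grid_size = 40)
  expect_equal(unname(st$param_point), c(1.5, 3.0), tolerance = 1e-12)
  expect_gt(abs(sum(st$direction * c(1, 0, 0))), 0.99)
  expect_lt(abs(st$value - 0.747), 0.005)
  expect_equal(length(st$skipped), 0)
  # the optimum beats random (parameter, direction) samples
  set.seed(17)
  for (i in 1:8) {
    pp <- c(kr = runif(1, 0.5, 1.5), RT = runif(1, 0.5, 3.0))
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    ds <- difference_system(mods$model1, mods$model2, params1 = pp, params2 = pp,
                            guess1 = dicty_guess, guess2 = dicty_guess)
    tr <- simulate_difference_system(ds, common_ic = v, rtol = 1e-7)
    expect_lte(tr$l2_norm, st$value + 1e-3)
  }
})

test_that("enlarging the design space cannot reduce the achievable difference", {
  mods <- dictyostelium_models("structural_design")
  st <- brute_force_structural_search(mods$model1, mods$model2,
                                      param_grid = 3, grid_size = 40)
  br <- brute_force_ic_search(dicty_ds(), grid_size = 40)
  expect_gte(st$value + 1e-6, br$value)
})

test_that("a fully collapsed box delegates to the plain storage certificate", {
  mods <- dictyostelium_models()
  box <- list(kr = c(1, 1), RT = c(23 / 30, 23 / 30))
  cert <- storage_structural(mods$model1, mods$model2, box, alpha = 0.1)
  expect_equal(cert$kind, "ic")
  ext <- extract_structural_optimum(cert, beta = 1)
  expect_gt(abs(sum(ext$direction * c(1, 0, 0))), 0.999)
  expect_equal(unname(ext$param_point), c(1, 23 / 30))
})
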