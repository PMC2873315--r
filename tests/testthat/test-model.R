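# model declaration, steady states, concatenation, fixtures, spec I/O

test_that("model validation catches undeclared symbols and bad boxes", {
  expect_error(ode_model("x", drift = "-x + Z", output_map = "x"),
               class = "discrim_validation_error")
  expect_error(ode_model("x", drift = "-x", output_map = "x",
                         param_boxes = list(k = c(2, 1))),
               class = "discrim_validation_error")
  expect_error(ode_model("x", drift = "-x", output_map = "x",
                         param_boxes = list(k = c(-1, 1))),
               class = "discrim_validation_error")
  # a degenerate box collapses to a fixed parameter value
  m <- ode_model("x", params = c(k = 0), drift = "-k*x", output_map = "x",
                 param_boxes = list(k = c(2, 2)))
  expect_null(m$param_boxes)
  expect_equal(m$params[["k"]], 2)
})

test_that("a minimal one-state spec round-trips through JSON and YAML", {
  m <- ode_model("x", drift = "-x", output_map = "x", name = "minimal")
  expect_equal(m$n, 1); expect_equal(m$l, 1)
  for (ext in c("json", "yaml")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_model_spec(m, path)
    m2 <- parse_model_spec(path)
    expect_equal(m2$states, m$states)
    expect_equal(m2$drift, m$drift)
    expect_equal(m2$output_map, m$output_map)
  }
})

test_that("rational right-hand sides are accepted but flagged", {
  m <- ode_model("s", params = c(V = 1, K = 2), drift = "-V*s/(K + s)",
                 output_map = "s")
  expect_false(m$polynomial)
})

test_that("the chemotaxis fixture reproduces the printed steady state", {
  ss <- compute_steady_state(dictyostelium_models()$model1, guess = dicty_guess)
  # activator and inhibitor levels from the rate balance; response regulator
  # equilibrium printed as 0.1
  expect_equal(unname(ss$x_star), c(0.3, 2, 0.1), tolerance = 1e-9)
  expect_true(all(Re(ss$eigenvalues) < 0))
  # the two rivals share I* = 2 by construction of the rate constants
  ss2 <- compute_steady_state(dictyostelium_models()$model2, guess = dicty_guess)
  expect_equal(unname(ss2$x_star), c(0.3, 2, 0.1), tolerance = 1e-9)
})

test_that("structural variant carries the declared parameter boxes", {
  mods <- dictyostelium_models("structural_design")
  expect_equal(mods$model1$param_boxes$kr, c(0.5, 1.5))
  expect_equal(mods$model1$param_boxes$RT, c(0.5, 3.0))
})

test_that("steady-state solve rejects unstable equilibria", {
  m <- ode_model("x", drift = "x", output_map = "x")
  expect_error(compute_steady_state(m, guess = 0),
               class = "discrim_stability_error")
})

test_that("shifted drift vanishes at the origin across the parameter box", {
  mods <- dictyostelium_models("structural_design")
  set.seed(42)
  origin <- stats::setNames(rep(0, 3), mods$model1$states)
  for (i in 1:25) {
    pp <- c(kr = runif(1, 0.5, 1.5), RT = runif(1, 0.5, 3.0))
    for (mod in mods) {
      sm <- compute_steady_state(mod, guess = dicty_guess, params = pp)
      resid <- vapply(sm$drift_shift, function(p)
        discrimODE:::poly_eval(p, origin), 0)
      expect_lt(max(abs(resid)), 1e-10)
    }
  }
  # both rivals share the steady state everywhere in the box
  for (i in 1:10) {
    pp <- c(kr = runif(1, 0.5, 1.5), RT = runif(1, 0.5, 3.0))
    s1 <- compute_steady_state(mods$model1, guess = dicty_guess, params = pp)
    s2 <- compute_steady_state(mods$model2, guess = dicty_guess, params = pp)
    expect_equal(s1$x_star, s2$x_star, tolerance = 1e-9)
  }
})

test_that("concatenation demands matching dimensions and kills the output at 0", {
  ds <- dicty_ds()
  expect_equal(ds$n1 + ds$n2, 6)
  y0 <- vapply(ds$output, function(p)
    discrimODE:::poly_eval(p, stats::setNames(rep(0, 6), ds$vars)), 0)
  expect_equal(max(abs(y0)), 0, tolerance = 1e-12)

  m1 <- ode_model("x", drift = "-x", output_map = "x")
  m3 <- ode_model("x", drift = "-x", output_map = c("x", "x", "x"))
  s1 <- compute_steady_state(m1, guess = 0.2)
  s3 <- compute_steady_state(m3, guess = 0.2)
  expect_error(concatenate_models(s1, s3), class = "discrim_validation_error")
})

test_that("a model concatenated with itself has identically zero output", {
  m <- dictyostelium_models()$model1
  ds <- difference_system(m, m, guess1 = dicty_guess, guess2 = dicty_guess)
  tr <- simulate_difference_system(ds, common_ic = c(0.4, -0.2, 0.05),
                                   t_end = 50)
  expect_lt(tr$l2_norm, 1e-7)
})

test_that("shipped model-spec documents parse to the built-in fixtures", {
  f1 <- system.file("extdata", "dictyostelium_model1.json", package = "discrimODE")
  m1 <- parse_model_spec(f1)
  ref <- dictyostelium_models()$model1
  expect_equal(m1$states, ref$states)
  expect_equal(m1$params[names(ref$params)], ref$params, tolerance = 1e-12)
  fS <- system.file("extdata", "dictyostelium_model1_structural.json",
                    package = "discrimODE")
  mS <- parse_model_spec(fS)
  expect_equal(mS$param_boxes$kr, c(0.5, 1.5))
  expect_equal(mS$param_boxes$RT, c(0.5, 3.0))
})

test_that("rational kinetics run through simulation but are refused by the SOS engine", {
  m1 <- ode_model("s", params = c(V = 1, K = 2, d = 0.5),
                  drift = "-V*s/(K + s) - d*s", input_map = "1",
                  output_map = "s", basal_input = 0.3, name = "MM-1")
  m2 <- ode_model("s", params = c(d = 0.9), drift = "-d*s", input_map = "1",
                  output_map = "s", basal_input = 0.3, name = "lin-2")
  # shared steady state: pick the linear decay so both rest at the same point
  s1 <- compute_steady_state(m1, guess = 0.5)
  d2 <- (1 * s1$x_star / (2 + s1$x_star) + 0.5 * s1$x_star) / s1$x_star
  m2 <- ode_model("s", params = c(d = unname(d2)), drift = "-d*s",
                  input_map = "1", output_map = "s", basal_input = 0.3,
                  name = "lin-2")
  ds <- difference_system(m1, m2, guess1 = 0.5, guess2 = 0.5)
  expect_false(ds$polynomial)
  tr <- simulate_difference_system(ds, common_ic = 0.1)
  expect_gt(tr$l2_norm, 0)
  expect_silent(frequency_peak(linearize(ds)))
  expect_error(storage_for_ic_design(ds), class = "discrim_validation_error")
})

test_that("steady-state reports serialize with eigenvalues and provenance", {
  sm <- compute_steady_state(dictyostelium_models()$model1, guess = dicty_guess)
  path <- tempfile(fileext = ".json")
  write_steady_state_report(sm, path)
  rep <- jsonlite::fromJSON(path)
  expect_equal(rep$steady_state$Rstar, 0.1, tolerance = 1e-9)
  expect_true(all(rep$jacobian_eigenvalues$re < 0))
})
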