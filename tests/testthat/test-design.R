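# high-level design workflows and reports

test_that("linear-route initial-condition design reports the printed experiment", {
  mods <- dictyostelium_models()
  rep1 <- design_initial_condition(mods$model1, mods$model2, method = "linear")
  expect_gt(abs(sum(rep1$direction * c(1, 0, 0))), 0.999)
  expect_lt(abs(rep1$value - 0.729), 0.005)
  expect_output(print(rep1), "initial_condition")
})

test_that("designs are reproducible to full precision", {
  mods <- dictyostelium_models()
  r1 <- design_initial_condition(mods$model1, mods$model2, method = "linear")
  r2 <- design_initial_condition(mods$model1, mods$model2, method = "linear")
  expect_identical(r1$direction, r2$direction)
  expect_lt(abs(r1$value - r2$value), 1e-9)
})

test_that("identical rivals surface a degenerate-design error", {
  m <- dictyostelium_models()$model1
  expect_error(design_initial_condition(m, m, method = "linear"),
               class = "discrim_degenerate_error")
})

test_that("small perturbations scale the design value linearly", {
  mods <- dictyostelium_models()
  r <- design_initial_condition(mods$model1, mods$model2, beta = 0.01,
                                method = "linear")
  expect_gt(abs(sum(r$direction * c(1, 0, 0))), 0.999)
  # in the linear regime the simulated value is beta * sqrt(lambda-hat)
  expect_equal(r$value / 0.01, r$linear_prediction / 0.01, tolerance = 0.02)
})

test_that("input design ranks stimuli and handles zero energy", {
  mods <- dictyostelium_models()
  r <- design_input(mods$model1, mods$model2,
                    candidate_kinds = c("sine", "constant"))
  expect_equal(r$recommended, "sine")
  expect_equal(r$omega0, 0.4470, tolerance = 2e-4)
  expect_lt(abs(r$candidates$value[r$candidates$kind == "sine"] - 0.472),
            0.005)
  rz <- design_input(mods$model1, mods$model2, energy = 0,
                     candidate_kinds = c("sine", "constant"))
  expect_true(all(rz$candidates$value < 1e-8))
  expect_error(design_input(mods$model1, mods$model2,
                            candidate_kinds = character(0)),
               class = "discrim_validation_error")
})

test_that("input design for the response regulator uses its own critical frequency", {
  mods <- dictyostelium_models()
  r <- design_input(mods$model1, mods$model2, output = "Rstar",
                    candidate_kinds = c("sine", "constant"))
  expect_equal(r$omega0, 0.3853, tolerance = 2e-4)
  expect_lt(abs(r$candidates$value[r$candidates$kind == "sine"] - 0.0195),
            0.005)
})

test_that("structural design over a point box matches the plain initial-condition design", {
  mods <- dictyostelium_models()
  box <- list(kr = c(1, 1), RT = c(23 / 30, 23 / 30))
  rs <- design_structural(mods$model1, mods$model2, box, method = "brute",
                          param_grid = 2, grid_size = 60)
  ri <- design_initial_condition(mods$model1, mods$model2, method = "brute",
                                 grid_size = 60)
  expect_equal(rs$value, ri$value, tolerance = 1e-3)
  expect_equal(unname(rs$param_point), c(1, 23 / 30))
})

test_that("reports serialize to JSON", {
  mods <- dictyostelium_models()
  r <- design_initial_condition(mods$model1, mods$model2, method = "linear")
  path <- tempfile(fileext = ".json")
  write_design_report(r, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$task, "initial_condition")
  expect_equal(as.numeric(back$value), r$value, tolerance = 1e-12)
})
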