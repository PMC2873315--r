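# Shared fixtures, built in code and cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- make()
  .fixture_cache[[key]]
}

dicty_guess <- c(1, 1, 0.5)

dicty_ds <- function() cached("dicty_ds", function() {
  mods <- dictyostelium_models()
  difference_system(mods$model1, mods$model2,
                    guess1 = dicty_guess, guess2 = dicty_guess)
})

dicty_lin <- function() cached("dicty_lin", function() linearize(dicty_ds()))

dicty_storage <- function() cached("dicty_storage", function()
  storage_for_ic_design(dicty_ds(), alpha = 0.1, deg_S = 2))

# the linearized rivals expressed as (linear) models of their own, used for
# simulation oracles of linear-systems identities
dicty_linear_models <- function() cached("dicty_linear", function() {
  ds <- dicty_ds()
  build <- function(sm, name) {
    A <- sm$A_lin; B <- sm$B_lin
    st <- c("A", "I", "Rstar")
    drift <- vapply(1:3, function(i)
      paste(sprintf("(%.15g)*%s", A[i, ], st), collapse = " + "), "")
    ode_model(st, drift = drift,
              input_map = sprintf("(%.15g)", B[, 1]),
              output_map = st, basal_input = 0, name = name)
  }
  list(model1 = build(ds$m1, "linearized model 1"),
       model2 = build(ds$m2, "linearized model 2"))
})

dicty_linear_ds <- function() cached("dicty_linear_ds", function() {
  m <- dicty_linear_models()
  difference_system(m$model1, m$model2, guess1 = rep(0, 3), guess2 = rep(0, 3))
})

# scalar rival pair x' = -x + u vs x' = -2x + u, y = x
scalar_pair_ds <- function() cached("scalar_pair", function() {
  m1 <- ode_model("x", params = c(a = 1), drift = "-a*x", input_map = "1",
                  output_map = "x", basal_input = 0, name = "scalar a=1")
  m2 <- ode_model("x", params = c(a = 2), drift = "-a*x", input_map = "1",
                  output_map = "x", basal_input = 0, name = "scalar a=2")
  difference_system(m1, m2, guess1 = 0.5, guess2 = 0.5)
})

# a hand-built (non-solved) difference system, for paths that must bypass the
# steady-state machinery (e.g. infeasibility of storage for unstable drift)
fake_scalar_ds <- function(a) {
  vars <- c("x_m1", "x_m2")
  drift <- list(poly_parse("a*x_m1", vars, c(a = a)),
                poly_parse("-1*x_m2", vars))
  out <- list(poly_parse("x_m1 - x_m2", vars))
  structure(list(m1 = NULL, m2 = NULL, vars = vars, n1 = 1, n2 = 1,
                 q = 0, l = 1, output_names = "y",
                 drift = drift, output = out, input_map = NULL,
                 polynomial = TRUE),
            class = "diff_system")
}

dicty_gain <- function() cached("dicty_gain", function()
  suppressWarnings(l2_gain_bound(dicty_ds(), alpha = 0.1, deg_S = 2)))
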