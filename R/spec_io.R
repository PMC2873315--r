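# Declarative model-spec documents (JSON or YAML).
#
# Schema: keys `states`, `params` (scalar value or `[low, high]` interval),
# `drift`, `input_map` (row-major `n x q`), `output_map`, `basal_input`,
# optional `name`.  Expressions use the plain infix grammar understood by
# the parser in poly.R.

#' Read a model from a declarative spec document
#'
#' @param x path to a `.json`/`.yaml`/`.yml` file, or an already-parsed list
#' @return an [ode_model()]
#' @export
parse_model_spec <- function(x) {
  doc <- x
  if (is.character(x) && length(x) == 1) {
    if (grepl("\\.ya?ml$", x, ignore.case = TRUE)) doc <- yaml::read_yaml(x)
    else doc <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  }
  if (!is.list(doc)) stop(validation_error("model spec must be a document (list)"))
  for (field in c("states", "drift", "output_map"))
    if (is.null(doc[[field]]))
      stop(validation_error(sprintf("model spec is missing required field '%s'", field)))

  params <- numeric(0)
  boxes <- NULL
  for (nm in names(doc$params)) {
    v <- doc$params[[nm]]
    if (length(v) == 1) params[nm] <- as.numeric(v)
    else if (length(v) == 2) {
      boxes[[nm]] <- as.numeric(v)
      params[nm] <- mean(as.numeric(v))   # nominal value: box midpoint
    } else stop(validation_error(sprintf("parameter '%s' must be a value or [low, high]", nm)))
  }
  if (!is.null(doc$nominal))
    params[names(doc$nominal)] <- as.numeric(doc$nominal)

  input_map <- doc$input_map
  if (!is.null(input_map) && !is.matrix(input_map)) {
    n <- length(doc$states)
    input_map <- matrix(as.character(unlist(input_map)), nrow = n, byrow = TRUE)
  }
  ode_model(states = doc$states, params = params,
            drift = as.character(doc$drift),
            input_map = input_map,
            output_map = as.character(doc$output_map),
            basal_input = if (is.null(doc$basal_input)) numeric(0) else as.numeric(doc$basal_input),
            param_boxes = boxes,
            name = if (is.null(doc$name)) "model" else doc$name)
}

#' Write a model back to a spec document
#'
#' Round-trips with [parse_model_spec()]: the document it writes parses back
#' to an equivalent model.
#'
#' @param model an [ode_model()]
#' @param path output path; format chosen by extension (`.json` or `.yaml`)
#' @export
write_model_spec <- function(model, path) {
  params <- as.list(model$params)
  nominal <- list()
  for (nm in names(model$param_boxes)) {
    nominal[[nm]] <- model$params[[nm]]
    params[[nm]] <- model$param_boxes[[nm]]
  }
  doc <- list(name = model$name, states = model$states, params = params,
              drift = model$drift,
              input_map = if (model$q > 0) apply(model$input_map, 1, identity, simplify = FALSE) else NULL,
              output_map = model$output_map, basal_input = model$basal_input)
  if (length(nominal)) doc$nominal <- nominal
  doc <- Filter(Negate(is.null), doc)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::write_yaml(doc, path)
  else jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a steady-state shift report
#'
#' Serializes the provenance of a steady-state shift — the model name, the
#' root and its residual, the Jacobian eigenvalues and the
#' deviation-coordinate convention — as JSON.
#'
#' @param shifted a [compute_steady_state()] result
#' @param path output file
#' @export
write_steady_state_report <- function(shifted, path) {
  rep <- list(
    model = shifted$model$name,
    steady_state = as.list(shifted$x_star),
    residual = shifted$residual,
    jacobian_eigenvalues = lapply(shifted$eigenvalues, function(z)
      list(re = Re(z), im = Im(z))),
    convention = "deviation coordinates: x_reported = x_raw - steady_state; outputs shifted so h(0) = 0"
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The two rival chemotaxis adaptation models of Dictyostelium discoideum
#'
#' Both models describe perfect adaptation of the chemotactic response
#' regulator: an activator `A` driven by the cAMP ligand `S` activates `R*`
#' (with `R_T = R + R*` conserved), and an inhibitor `I` deactivates it.  In
#' Model 1 the inhibitor is produced directly from the ligand signal
#' (`dI/dt = ki*S - kmi*I`); in Model 2 it is produced indirectly through the
#' activator (`dI/dt = kip*A - kmi*I`).  With the shipped rate constants the
#' two models share the same unique steady state (`A* = 0.3`, `I* = 2`,
#' `R** = 0.1` at basal input `S0 = 0.2`), so their outputs are
#' indistinguishable at rest — the textbook model-discrimination situation.
#' The inhibitor production constants are pinned by that shared-steady-state
#' requirement: `I* = ki*S0/kmi = 2` in Model 1 forces `ki = 1`, and
#' `I* = kip*A*/kmi = 2` in Model 2 forces `kip = 2/3` given `A* = 0.3`.
#'
#' @param variant `"fixed_params"` for the nominal parameter set, or
#'   `"structural_design"` to additionally mark `kr` (settable in
#'   `[0.5, 1.5]`) and `RT` (settable in `[0.5, 3.0]`) as experimentally
#'   adjustable
#' @return list with components `model1` and `model2`
#' @export
dictyostelium_models <- function(variant = c("fixed_params", "structural_design")) {
  variant <- match.arg(variant)
  boxes <- if (variant == "structural_design")
    list(kr = c(0.5, 1.5), RT = c(0.5, 3.0)) else NULL
  common <- list(
    states = c("A", "I", "Rstar"),
    output_map = c("A", "I", "Rstar"),
    basal_input = 0.2,
    param_boxes = boxes
  )
  p1 <- c(kr = 1, kmr = 1, ka = 3, kma = 2, ki = 1, kmi = 0.1, RT = 23 / 30)
  p2 <- c(kr = 1, kmr = 1, ka = 3, kma = 2, kip = 2 / 3, kmi = 0.1, RT = 23 / 30)
  m1 <- do.call(ode_model, c(common, list(
    params = p1,
    drift = c("-kma*A", "-kmi*I", "kr*A*(RT - Rstar) - kmr*I*Rstar"),
    input_map = c("ka", "ki", "0"),
    name = "Dictyostelium model 1 (ligand-driven inhibitor)")))
  m2 <- do.call(ode_model, c(common, list(
    params = p2,
    drift = c("-kma*A", "kip*A - kmi*I", "kr*A*(RT - Rstar) - kmr*I*Rstar"),
    input_map = c("ka", "0", "0"),
    name = "Dictyostelium model 2 (activator-driven inhibitor)")))
  list(model1 = m1, model2 = m2)
}

# shared fixture helper: shift both rivals at given box-parameter values
dicty_diff_system <- function(params = NULL, variant = "fixed_params") {
  mods <- dictyostelium_models(variant)
  guess <- c(0.3, 2, 0.1)
  difference_system(mods$model1, mods$model2,
                    params1 = params, params2 = params,
                    guess1 = guess, guess2 = guess)
}
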