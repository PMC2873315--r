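# High-level experiment-design workflows: each function runs one of the three
# design methods end to end (linearized, SOS and/or brute-force routes),
# validates the designed perturbation by nonlinear simulation, and returns a
# classed report.

.new_report <- function(task, config, ...) {
  structure(c(list(task = task, config = config,
                   timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
              list(...)),
            class = "design_report")
}

#' Design the most discriminating common initial condition
#'
#' Finds the common unit direction `x1(0) = x2(0) = beta * v` that maximizes
#' the L2 norm of the output difference of the two rival models released from
#' steady state with no input.  Routes: `"linear"` (restricted-gramian
#' eigenproblem), `"sos"` (storage-function level-set extraction), `"brute"`
#' (simulation over a sphere grid), or `"all"`.  Every candidate direction is
#' re-scored by nonlinear simulation; the recommendation is the best
#' simulated candidate.
#'
#' @param model1,model2 rival [ode_model()]s
#' @param beta perturbation magnitude
#' @param method design route(s)
#' @param output output selector used for the design objective
#' @param alpha,deg_S SOS storage options (see [storage_for_ic_design()])
#' @param grid_size brute-force sphere grid size
#' @param seed recorded in the report for provenance (the routes themselves
#'   are deterministic)
#' @return a `design_report`
#' @export
design_initial_condition <- function(model1, model2, beta = 1,
                                     method = c("all", "linear", "sos", "brute"),
                                     output = NULL, alpha = 0.1, deg_S = 2,
                                     grid_size = 300, seed = NULL) {
  method <- match.arg(method)
  config <- list(beta = beta, method = method, output = output, alpha = alpha,
                 deg_S = deg_S, grid_size = grid_size, seed = seed,
                 rtol = 1e-10)
  ds <- difference_system(model1, model2)
  routes <- list()
  if (method %in% c("all", "linear")) {
    lin <- linearize(ds)
    gd <- observability_gramian(lin, output)
    od <- optimal_common_initial_direction(gd)
    routes$linear <- list(direction = od$direction,
                          energy_bound = od$energy_bound * beta^2,
                          tie = od$tie)
  }
  sos_bound <- NULL
  if (method %in% c("all", "sos")) {
    cert <- storage_for_ic_design(ds, alpha = alpha, deg_S = deg_S)
    ext <- extract_optimal_ic(cert, beta = beta)
    routes$sos <- list(direction = ext$direction,
                       energy_bound = ext$energy_bound,
                       route = ext$route, certificate = cert)
    sos_bound <- ext$energy_bound
  }
  if (method %in% c("all", "brute")) {
    br <- brute_force_ic_search(ds, beta = beta, grid_size = grid_size,
                                output = output)
    routes$brute <- list(direction = br$direction, value = br$value)
  }
  # score every candidate by nonlinear simulation
  score <- function(v) {
    tr <- simulate_difference_system(ds, common_ic = beta * v, output = output,
                                     rtol = 1e-10)
    signal_l2_norm(tr)
  }
  for (nm in names(routes)) routes[[nm]]$simulated <- score(routes[[nm]]$direction)
  best <- names(routes)[which.max(vapply(routes, `[[`, 0, "simulated"))]
  dirs <- lapply(routes, `[[`, "direction")
  agree <- if (length(dirs) > 1) {
    combn(names(dirs), 2, function(pr)
      abs(sum(dirs[[pr[1]]] * dirs[[pr[2]]])), simplify = TRUE)
  } else NULL
  .new_report("initial_condition", config,
              routes = routes, recommended = best,
              direction = routes[[best]]$direction,
              value = routes[[best]]$simulated,
              linear_prediction = if (!is.null(routes$linear))
                sqrt(routes$linear$energy_bound) else NULL,
              sos_bound = if (!is.null(sos_bound)) sqrt(sos_bound) else NULL,
              agreement = agree,
              bound_ok = if (!is.null(sos_bound))
                routes[[best]]$simulated <= sqrt(sos_bound) * 1.05 + 1e-6 else NA)
}

#' Design the most discriminating stimulus profile
#'
#' Picks the stimulation frequency from the Bode-magnitude peak of the
#' linearized difference system (for the selected output), builds a library
#' of unit-energy candidate stimuli at that frequency, scores each by
#' nonlinear simulation of the output-difference L2 norm, and ranks them.
#'
#' @param model1,model2 rival [ode_model()]s
#' @param output output selector (both the critical frequency and the
#'   reported norms use these rows)
#' @param T_active stimulation window; inputs vanish afterwards
#' @param energy stimulus L2 norm (`0` gives all-zero scores)
#' @param candidate_kinds which stimulus shapes to score
#' @param sos_bound also compute the SOS L2-gain upper bound
#' @param alpha,deg_S options for the gain bound
#' @param seed recorded for provenance
#' @return a `design_report` with the per-candidate table (`candidates`)
#' @export
design_input <- function(model1, model2, output = NULL, T_active = 60,
                         energy = 1,
                         candidate_kinds = c("sine", "exp_mod_sine", "cosine",
                                             "damped_cosine", "square", "sinc",
                                             "constant"),
                         sos_bound = FALSE, alpha = 0.1, deg_S = 2,
                         seed = NULL) {
  if (length(candidate_kinds) < 1) stop(validation_error("no candidate kinds given"))
  if (T_active <= 0) stop(validation_error("T_active must be positive"))
  config <- list(output = output, T_active = T_active, energy = energy,
                 candidate_kinds = candidate_kinds, sos_bound = sos_bound,
                 alpha = alpha, deg_S = deg_S, seed = seed, rtol = 1e-10)
  ds <- difference_system(model1, model2)
  lin <- linearize(ds)
  fp <- frequency_peak(lin, output)
  vals <- numeric(length(candidate_kinds))
  sigs <- vector("list", length(candidate_kinds))
  for (i in seq_along(candidate_kinds)) {
    kind <- candidate_kinds[i]
    sig <- if (energy == 0) input_signal("zero", T_active = T_active) else
      input_signal(kind, omega = if (kind == "constant") NULL else fp$omega0,
                   T_active = T_active, energy = energy)
    tr <- simulate_difference_system(ds, input = sig, output = output, rtol = 1e-10)
    vals[i] <- signal_l2_norm(tr)
    sigs[[i]] <- sig
  }
  ord <- order(vals, decreasing = TRUE)
  tab <- data.frame(kind = candidate_kinds[ord], value = vals[ord],
                    normalized = if (energy > 0) vals[ord] / energy else 0,
                    row.names = NULL)
  gb <- if (sos_bound) l2_gain_bound(ds, alpha = alpha, deg_S = deg_S) else NULL
  .new_report("input", config,
              omega0 = fp$omega0, linear_gain = fp$gain, flat = fp$flat,
              candidates = tab, recommended = tab$kind[1],
              input = sigs[[ord[1]]], value = tab$value[1],
              linear_prediction = fp$gain * energy,
              gain_certificate = gb,
              sos_bound = if (!is.null(gb)) gb$gain * energy else NULL,
              bound_ok = if (!is.null(gb)) tab$value[1] <= gb$gain * energy + 1e-3 else NA)
}

#' Design the most discriminating structural (parameter) change
#'
#' Chooses settable parameter values inside their boxes together with the
#' optimal common initial perturbation, maximizing the simulated
#' output-difference norm.  Routes: `"brute"` (grid over the box and the
#' direction sphere, steady state re-shifted at every point), `"sos"`
#' (parametric storage certificate + dual extraction), or `"all"` (both,
#' cross-checked).
#'
#' @param model1,model2 rival [ode_model()]s carrying parameter boxes
#' @param param_box named list of intervals; defaults to the models' boxes
#' @param beta common perturbation magnitude
#' @param method design route(s)
#' @param output output selector
#' @param alpha,deg_p SOS options (see [storage_structural()])
#' @param param_grid,grid_size brute-force grid resolutions
#' @param seed recorded for provenance
#' @return a `design_report`
#' @export
design_structural <- function(model1, model2, param_box = NULL, beta = 1,
                              method = c("all", "sos", "brute"), output = NULL,
                              alpha = 0.1, deg_p = 2, param_grid = 5,
                              grid_size = 60, seed = NULL) {
  method <- match.arg(method)
  if (is.null(param_box)) param_box <- model1$param_boxes
  if (is.null(param_box) || length(param_box) == 0)
    stop(validation_error("param_box is empty"))
  config <- list(param_box = param_box, beta = beta, method = method,
                 output = output, alpha = alpha, deg_p = deg_p,
                 param_grid = param_grid, grid_size = grid_size, seed = seed,
                 rtol = 1e-10)
  routes <- list()
  if (method %in% c("all", "brute")) {
    br <- brute_force_structural_search(model1, model2, param_box, beta = beta,
                                        param_grid = param_grid,
                                        grid_size = grid_size, output = output)
    routes$brute <- list(param_point = br$param_point, direction = br$direction,
                         value = br$value, skipped = br$skipped)
  }
  if (method %in% c("all", "sos")) {
    cert <- storage_structural(model1, model2, param_box, alpha = alpha,
                               deg_p = deg_p)
    ext <- extract_structural_optimum(cert, beta = beta)
    routes$sos <- list(param_point = ext$param_point, direction = ext$direction,
                       energy_bound = ext$energy_bound, route = ext$route,
                       certificate = cert)
  }
  score <- function(pp, v) {
    ds <- difference_system(model1, model2, params1 = pp, params2 = pp)
    tr <- simulate_difference_system(ds, common_ic = beta * v, output = output,
                                     rtol = 1e-10)
    signal_l2_norm(tr)
  }
  for (nm in names(routes))
    routes[[nm]]$simulated <- score(routes[[nm]]$param_point, routes[[nm]]$direction)
  best <- names(routes)[which.max(vapply(routes, `[[`, 0, "simulated"))]
  .new_report("structural", config,
              routes = routes, recommended = best,
              param_point = routes[[best]]$param_point,
              direction = routes[[best]]$direction,
              value = routes[[best]]$simulated,
              sos_bound = if (!is.null(routes$sos))
                sqrt(routes$sos$energy_bound) else NULL)
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report: %s>\n", x$task))
  if (!is.null(x$direction))
    cat("  direction: (", paste(sprintf("%.4f", x$direction), collapse = ", "), ")\n", sep = "")
  if (!is.null(x$param_point))
    cat("  parameters:", paste(sprintf("%s = %g", names(x$param_point), x$param_point),
                               collapse = ", "), "\n")
  if (!is.null(x$omega0))
    cat(sprintf("  critical frequency omega0 = %.6g rad/time (linear gain %.6g)\n",
                x$omega0, x$linear_gain))
  if (!is.null(x$candidates)) {
    cat("  candidate stimuli (simulated ||y1 - y2||_2):\n")
    for (i in seq_len(nrow(x$candidates)))
      cat(sprintf("    %-14s %.4g\n", x$candidates$kind[i], x$candidates$value[i]))
  }
  cat(sprintf("  simulated ||y1 - y2||_2 = %.6g", x$value))
  if (!is.null(x$recommended) && is.character(x$recommended))
    cat(sprintf("   [recommended: %s]", x$recommended))
  cat("\n")
  if (!is.null(x$sos_bound))
    cat(sprintf("  SOS bound on ||y||_2: %.6g (holds: %s)\n", x$sos_bound,
                if (isTRUE(x$bound_ok)) "yes" else if (isFALSE(x$bound_ok)) "NO" else "n/a"))
  invisible(x)
}

#' @export
summary.design_report <- function(object, ...) {
  print(object)
  if (!is.null(object$routes)) {
    cat("  routes:\n")
    for (nm in names(object$routes)) {
      r <- object$routes[[nm]]
      cat(sprintf("    %-7s direction (%s)  simulated %.6g\n", nm,
                  paste(sprintf("%.4f", r$direction), collapse = ", "),
                  r$simulated))
    }
    if (!is.null(object$agreement))
      cat("  pairwise |cos angle| between route directions:",
          paste(sprintf("%.6f", object$agreement), collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
plot.design_report <- function(x, model1, model2, ...) {
  pp <- x$param_point
  ds <- difference_system(model1, model2, params1 = pp, params2 = pp)
  tr <- if (x$task == "input")
    simulate_difference_system(ds, input = x$input, output = x$config$output)
  else
    simulate_difference_system(ds, common_ic = x$config$beta * x$direction,
                               output = x$config$output)
  plot(tr, main = paste("designed experiment:", x$task), ...)
  invisible(tr)
}

#' Serialize a design report to JSON
#'
#' @param report a `design_report`
#' @param path output file
#' @export
write_design_report <- function(report, path) {
  clean <- rapply(unclass(report), function(z) {
    if (is_polyform(z)) format(z) else z
  }, how = "replace",
  classes = c("numeric", "character", "logical", "integer", "polyform"))
  drop_heavy <- function(l) {
    if (!is.list(l)) return(l)
    l$certificate <- NULL; l$grams <- NULL
    lapply(l, drop_heavy)
  }
  jsonlite::write_json(drop_heavy(clean), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
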