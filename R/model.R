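# Rival ODE models, steady-state shifting, and the concatenated difference
# system.
#
# A model is   dx/dt = f(x) + g(x) u,   y = h(x)
# with polynomial (or rational) right-hand sides over declared states and
# named parameters.  All downstream analysis works in deviation coordinates:
# the investigated steady state is moved to the origin, where the two rival
# models' outputs agree, and the concatenated system's output is the
# difference y1 - y2 whose L2 norm every design method maximizes.

#' Declare an ODE model
#'
#' @param states character vector of state names
#' @param params named numeric vector of parameter values
#' @param drift character vector (length `n`) of drift expressions `f(x)`
#'   in the states and parameters, using the infix grammar `+ - * / ^ ( )`
#' @param input_map character matrix (`n x q`, or a length-`n` vector for a
#'   single input) giving `g(x)`; `NULL` for an autonomous model
#' @param output_map character vector (length `l >= 1`) giving `h(x)`
#' @param basal_input numeric vector (length `q`) of basal input levels at
#'   which the investigated steady state holds
#' @param param_boxes named list of closed intervals `c(lo, hi)` for the
#'   parameters an experimenter may set (structural design); intervals with
#'   `lo == hi` are collapsed into fixed parameter values
#' @param name label used in printing and reports
#' @return an object of class `ode_model`
#' @export
ode_model <- function(states, params = numeric(0), drift, input_map = NULL,
                      output_map, basal_input = numeric(0),
                      param_boxes = NULL, name = "model") {
  states <- as.character(states)
  n <- length(states)
  if (n < 1) stop(validation_error("at least one state is required"))
  if (length(drift) != n) stop(validation_error("drift must have one expression per state"))
  if (length(output_map) < 1) stop(validation_error("at least one output is required"))
  if (anyDuplicated(c(states, names(params))))
    stop(validation_error("state and parameter names must be distinct"))

  if (!is.null(param_boxes)) {
    for (nm in names(param_boxes)) {
      iv <- as.numeric(param_boxes[[nm]])
      if (length(iv) != 2 || is.na(iv[1]) || iv[2] < iv[1] || iv[1] < 0)
        stop(validation_error(sprintf(
          "parameter box '%s' must be a closed interval [a, b] with b >= a >= 0", nm)))
      if (iv[1] == iv[2]) {        # degenerate box: fix the value
        params[[nm]] <- iv[1]
        param_boxes[[nm]] <- NULL
      } else param_boxes[[nm]] <- iv
    }
    if (length(param_boxes) == 0) param_boxes <- NULL
  }

  if (is.null(input_map)) input_map <- matrix(character(0), n, 0)
  if (!is.matrix(input_map)) input_map <- matrix(input_map, ncol = 1)
  if (nrow(input_map) != n) stop(validation_error("input_map must have one row per state"))
  q <- ncol(input_map)
  if (length(basal_input) != q)
    stop(validation_error("basal_input length must equal the number of inputs"))

  known <- c(states, names(params))
  check_symbols <- function(exprs, field) {
    for (s in exprs) {
      syms <- all.vars(str2lang(s))
      bad <- setdiff(syms, known)
      if (length(bad))
        stop(validation_error(sprintf("undeclared symbol '%s' in %s expression '%s'",
                                      bad[1], field, s)))
    }
  }
  check_symbols(drift, "drift")
  if (q > 0) check_symbols(as.vector(input_map), "input_map")
  check_symbols(output_map, "output_map")

  parse_set <- function(exprs) {
    polys <- vector("list", length(exprs))
    rational <- FALSE
    for (i in seq_along(exprs)) {
      polys[[i]] <- tryCatch(poly_parse(exprs[i], states, params),
                             discrim_rational_error = function(e) { rational <<- TRUE; NULL })
    }
    list(polys = if (rational) NULL else polys, rational = rational)
  }
  dp <- parse_set(drift)
  gp <- if (q > 0) parse_set(as.vector(input_map)) else list(polys = list(), rational = FALSE)
  hp <- parse_set(output_map)
  polynomial <- !(dp$rational || gp$rational || hp$rational)

  structure(list(
    name = name, states = states, n = n, q = q, l = length(output_map),
    params = params, param_boxes = param_boxes,
    drift = drift, input_map = input_map, output_map = output_map,
    basal_input = as.numeric(basal_input),
    drift_poly = dp$polys,
    input_poly = if (q > 0 && !gp$rational) matrix(gp$polys, nrow = n) else NULL,
    output_poly = hp$polys,
    polynomial = polynomial
  ), class = "ode_model")
}

validation_error <- function(msg) {
  errorCondition(msg, class = c("discrim_validation_error", "error"))
}

#' @export
print.ode_model <- function(x, ...) {
  cat(sprintf("<ode_model '%s'>  %d state(s), %d input(s), %d output(s)%s\n",
              x$name, x$n, x$q, x$l,
              if (x$polynomial) "" else "  [rational right-hand side]"))
  for (i in seq_len(x$n)) cat(sprintf("  d%s/dt = %s%s\n", x$states[i], x$drift[i],
    if (x$q > 0 && any(x$input_map[i, ] != "0"))
      paste0(" + (", paste(x$input_map[i, ], collapse = ", "), ") . u") else ""))
  cat("  y = (", paste(x$output_map, collapse = ", "), ")\n", sep = "")
  if (!is.null(x$param_boxes))
    for (nm in names(x$param_boxes))
      cat(sprintf("  %s in [%g, %g]\n", nm, x$param_boxes[[nm]][1], x$param_boxes[[nm]][2]))
  invisible(x)
}

# numeric evaluators (work for both polynomial and rational models)
.model_env <- function(model, params = NULL) {
  p <- model$params
  if (!is.null(params)) p[names(params)] <- params
  e <- new.env(parent = baseenv())
  for (nm in names(p)) assign(nm, p[[nm]], envir = e)
  e
}

.eval_exprs <- function(exprs_lang, env, x, states) {
  for (j in seq_along(states)) assign(states[j], x[j], envir = env)
  vapply(exprs_lang, function(ex) eval(ex, env), 0)
}

model_funs <- function(model, params = NULL) {
  env <- .model_env(model, params)
  dl <- lapply(model$drift, str2lang)
  gl <- if (model$q > 0) lapply(as.vector(model$input_map), str2lang) else list()
  hl <- lapply(model$output_map, str2lang)
  list(
    f = function(x) .eval_exprs(dl, env, x, model$states),
    g = function(x) matrix(.eval_exprs(gl, env, x, model$states), model$n, model$q),
    h = function(x) .eval_exprs(hl, env, x, model$states)
  )
}

# --- steady state -----------------------------------------------------------

#' Locate and shift a model's steady state to the origin
#'
#' Solves `f(x) + g(x) u0 = 0` at the basal input by damped Newton iteration
#' (with a relaxation-simulation fallback), verifies that the Jacobian at the
#' root is Hurwitz, and returns the model rewritten in deviation coordinates.
#'
#' @param model an [ode_model()]
#' @param guess starting point for the root solve (defaults to a vector of
#'   ones in the model's units)
#' @param params named numeric overrides of parameter values (e.g. a point in
#'   a structural-design box)
#' @param tol residual tolerance on `|f|` at the root
#' @return an object of class `shifted_model` with the steady state `x_star`,
#'   deviation-coordinate drift/output polynomials, the Jacobian `A_lin`, the
#'   input matrix `B_lin = g(x*)` and the Jacobian eigenvalues
#' @export
compute_steady_state <- function(model, guess = NULL, params = NULL, tol = 1e-11) {
  fs <- model_funs(model, params)
  u0 <- model$basal_input
  F <- function(x) {
    v <- fs$f(x)
    if (model$q > 0) v <- v + as.numeric(fs$g(x) %*% u0)
    v
  }
  J <- function(x) num_jacobian(F, x)
  if (is.null(guess)) guess <- rep(1, model$n)
  x <- as.numeric(guess)

  newton <- function(x, iters = 200) {
    for (it in seq_len(iters)) {
      r <- F(x)
      if (sqrt(sum(r^2)) < tol) return(x)
      step <- tryCatch(solve(J(x), -r), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lam <- 1
      repeat {
        xn <- x + lam * step
        if (sqrt(sum(F(xn)^2)) < sqrt(sum(r^2)) || lam < 1e-10) break
        lam <- lam / 2
      }
      if (lam < 1e-10) return(NULL)
      x <- xn
    }
    if (sqrt(sum(F(x)^2)) < tol) x else NULL
  }
  root <- newton(x)
  if (is.null(root)) {
    # relaxation fallback: integrate towards the attractor, then polish
    traj <- deSolve::ode(y = x, times = c(0, 50, 200), parms = NULL,
                         func = function(t, y, p) list(F(y)),
                         method = "lsoda", rtol = 1e-8, atol = 1e-10)
    root <- newton(as.numeric(traj[nrow(traj), -1]))
  }
  if (is.null(root))
    stop(errorCondition(sprintf("steady-state solve did not converge (residual %.3e)",
                                sqrt(sum(F(x)^2))),
                        class = c("discrim_convergence_error", "error")))
  A_lin <- J(root)
  ev <- eigen(A_lin, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop(errorCondition(sprintf(
      "Jacobian at the steady state is not Hurwitz (max Re eigenvalue %.3g); the design methods assume asymptotic stability",
      max(Re(ev))),
      class = c("discrim_stability_error", "error")))

  p_eff <- model$params
  if (!is.null(params)) p_eff[names(params)] <- params

  shift <- stats::setNames(root, model$states)
  drift_shift <- output_shift <- input_shift <- NULL
  if (model$polynomial) {
    # deviation drift: f(x~ + x*) + g(x~ + x*) u0, exact via affine substitution
    dpol <- lapply(model$drift, poly_parse, vars = model$states, consts = p_eff)
    hpol <- lapply(model$output_map, poly_parse, vars = model$states, consts = p_eff)
    gpol <- if (model$q > 0)
      lapply(as.vector(model$input_map), poly_parse, vars = model$states, consts = p_eff)
    else list()
    origin <- stats::setNames(rep(0, model$n), model$states)
    drift_shift <- lapply(seq_len(model$n), function(i) {
      p <- dpol[[i]]
      if (model$q > 0)
        for (k in seq_len(model$q))
          p <- poly_add(p, poly_scale(gpol[[(k - 1) * model$n + i]], u0[k]))
      ps <- poly_subst_affine(p, shift = shift)
      # remove the root-solve residual so the deviation drift vanishes
      # exactly at the origin (the residual is below `tol` by construction)
      ps <- poly_add(ps, poly_const(ps$vars, -poly_eval(ps, origin)))
      scale <- max(abs(ps$coef), 1e-300)
      poly_canon(ps, drop_tol = 1e-12 * scale)
    })
    output_shift <- lapply(hpol, function(p) {
      ps <- poly_subst_affine(p, shift = shift)
      ps <- poly_add(ps, poly_const(ps$vars, -poly_eval(p, shift)))
      scale <- max(abs(ps$coef), 1e-300)
      poly_canon(ps, drop_tol = 1e-12 * scale)
    })
    if (model$q > 0)
      input_shift <- matrix(lapply(gpol, poly_subst_affine, shift = shift), model$n)
    resid <- vapply(drift_shift, function(p) poly_eval(p, stats::setNames(rep(0, model$n), model$states)), 0)
    stopifnot(all(abs(resid) <= 1e-10))
  }

  structure(list(
    model = model, params = p_eff, x_star = shift,
    A_lin = A_lin, B_lin = if (model$q > 0) fs$g(root) else matrix(0, model$n, 0),
    C_lin = num_jacobian(fs$h, root),
    eigenvalues = ev, residual = sqrt(sum(F(root)^2)),
    drift_shift = drift_shift, output_shift = output_shift,
    input_shift = input_shift
  ), class = "shifted_model")
}

num_jacobian <- function(fn, x, eps = 1e-7) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  J
}

#' @export
print.shifted_model <- function(x, ...) {
  cat(sprintf("<shifted_model '%s'>  steady state shifted to the origin\n", x$model$name))
  cat("  x* =", paste(sprintf("%s = %.6g", names(x$x_star), x$x_star), collapse = ", "), "\n")
  cat("  Jacobian eigenvalues:",
      paste(sprintf("%.4g%+.4gi", Re(x$eigenvalues), Im(x$eigenvalues)), collapse = ", "), "\n")
  invisible(x)
}

# --- concatenated difference system ----------------------------------------

#' Concatenate two steady-state-shifted models into a difference system
#'
#' Stacks the deviation-coordinate dynamics of the two rivals and forms the
#' output `y = h1(x1) - h2(x2)`, which is identically zero at the combined
#' origin.  All design methods maximize the L2 norm of this output.
#'
#' @param shifted1,shifted2 objects from [compute_steady_state()]
#' @return an object of class `diff_system`
#' @export
concatenate_models <- function(shifted1, shifted2) {
  m1 <- shifted1$model; m2 <- shifted2$model
  if (m1$q != m2$q)
    stop(validation_error("input dimension mismatch between the two models"))
  if (m1$l != m2$l)
    stop(validation_error("output dimension mismatch between the two models"))
  vars <- c(paste0(m1$states, "_m1"), paste0(m2$states, "_m2"))
  n1 <- m1$n; n2 <- m2$n
  polynomial <- m1$polynomial && m2$polynomial

  lift <- function(p, which) {
    pv <- p
    pv$vars <- if (which == 1) paste0(p$vars, "_m1") else paste0(p$vars, "_m2")
    poly_extend_vars(pv, vars)
  }
  drift <- output <- input_map <- NULL
  if (polynomial) {
    drift <- c(lapply(shifted1$drift_shift, lift, which = 1),
               lapply(shifted2$drift_shift, lift, which = 2))
    h1 <- lapply(shifted1$output_shift, lift, which = 1)
    h2 <- lapply(shifted2$output_shift, lift, which = 2)
    output <- lapply(seq_len(m1$l), function(i) poly_sub(h1[[i]], h2[[i]]))
    if (m1$q > 0) {
      input_map <- matrix(vector("list", (n1 + n2) * m1$q), n1 + n2, m1$q)
      for (k in seq_len(m1$q)) {
        for (i in seq_len(n1)) input_map[[i, k]] <- lift(shifted1$input_shift[[i, k]], 1)
        for (i in seq_len(n2)) input_map[[n1 + i, k]] <- lift(shifted2$input_shift[[i, k]], 2)
      }
    }
    y0 <- vapply(output, function(p)
      poly_eval(p, stats::setNames(rep(0, n1 + n2), vars)), 0)
    stopifnot(all(abs(y0) <= 1e-10))
  }

  structure(list(
    m1 = shifted1, m2 = shifted2, vars = vars,
    n1 = n1, n2 = n2, q = m1$q, l = m1$l,
    output_names = m1$output_map,
    drift = drift, output = output, input_map = input_map,
    polynomial = polynomial,
    cache = new.env(parent = emptyenv())
  ), class = "diff_system")
}

#' @export
print.diff_system <- function(x, ...) {
  cat(sprintf("<diff_system>  %d + %d states, %d input(s), output y = y1 - y2 (l = %d)\n",
              x$n1, x$n2, x$q, x$l))
  cat(sprintf("  models: '%s' vs '%s'%s\n", x$m1$model$name, x$m2$model$name,
              if (x$polynomial) "" else "  [rational: simulation/linear methods only]"))
  invisible(x)
}

#' Shift both rival models to their steady states and concatenate them
#'
#' Convenience wrapper chaining [compute_steady_state()] on each model and
#' [concatenate_models()] on the results.
#'
#' @param model1,model2 rival [ode_model()]s
#' @param params1,params2 named parameter overrides per model
#' @param guess1,guess2 steady-state solve starting points
#' @return a `diff_system`
#' @export
difference_system <- function(model1, model2, params1 = NULL, params2 = NULL,
                              guess1 = NULL, guess2 = NULL) {
  concatenate_models(compute_steady_state(model1, guess1, params1),
                     compute_steady_state(model2, guess2, params2))
}
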