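# Nonlinear simulation of the difference system, L2 output norms with
# certified tails, and brute-force design oracles.

# compile one model's deviation dynamics and outputs into a single R
# function (x, u) -> c(dx, h(x)); the textual assembly avoids per-step
# environment juggling, which dominates integration cost otherwise
.compile_model_funs <- function(sm) {
  model <- sm$model
  n <- model$n; q <- model$q
  env <- .model_env(model, sm$params)
  terms <- vapply(seq_len(n), function(i) {
    ex <- paste0("(", model$drift[i], ")")
    if (q > 0) for (k in seq_len(q)) {
      gk <- model$input_map[i, k]
      if (gk != "0")
        ex <- paste0(ex, " + (", gk, ")*(", model$basal_input[k],
                     " + u[", k, "])")
    }
    ex
  }, "")
  body_text <- paste0(
    "function(x, u) {",
    paste(sprintf("%s <- x[%d] + %.17g", model$states, seq_len(n), sm$x_star),
          collapse = "; "),
    "; c(", paste(terms, collapse = ", "), ", ",
    paste0("(", model$output_map, ")", collapse = ", "), ") }")
  compiler::cmpfun(eval(parse(text = body_text), envir = env))
}

# deviation-coordinate RHS of the concatenated system, with input u(t) on top
# of the basal level
.diff_rhs <- function(ds, input = NULL) {
  if (!is.null(ds$cache) && !is.null(ds$cache$F1)) {
    F1 <- ds$cache$F1; F2 <- ds$cache$F2
  } else {
    F1 <- .compile_model_funs(ds$m1)
    F2 <- .compile_model_funs(ds$m2)
    if (!is.null(ds$cache)) { ds$cache$F1 <- F1; ds$cache$F2 <- F2 }
  }
  n1 <- ds$n1; n2 <- ds$n2; q <- ds$q; l <- ds$l
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  h1 <- n1 + seq_len(l); h2 <- n2 + seq_len(l)
  ufun <- if (is.null(input)) NULL else input$fun
  function(t, y, parms) {
    u <- if (is.null(ufun)) 0 else ufun(t)
    v1 <- F1(y[i1], u)
    v2 <- F2(y[i2], u)
    yd <- v1[h1] - v2[h2]
    list(c(v1[seq_len(n1)], v2[seq_len(n2)], sum(yd[parms$rows]^2)), ydiff = yd)
  }
}

# observability gramian of the linearization for the selected output rows;
# used to bound the post-horizon ("tail") output energy from the final state
# (cached per difference system and output selection)
.tail_gramian <- function(ds, rows) {
  key <- paste0("tail_", paste(rows, collapse = "_"))
  if (!is.null(ds$cache) && !is.null(ds$cache[[key]])) return(ds$cache[[key]])
  lin <- linearize(ds)
  C <- lin$C[rows, , drop = FALSE]
  P <- lyapunov_solve(lin$A, crossprod(C))
  if (!is.null(ds$cache)) ds$cache[[key]] <- P
  P
}

#' Simulate the nonlinear difference system
#'
#' Integrates both rival models (in deviation coordinates) from a common
#' perturbation and/or under a stimulus, accumulating the squared output
#' difference.  The horizon starts at `T_active + 10/|Re lambda_slow|` and is
#' extended by 50% until the linearization-based tail-energy estimate falls
#' below `1e-6` of the total, so the reported norm approximates the integral
#' to infinity.
#'
#' @param diff_system a [concatenate_models()] result
#' @param common_ic common initial perturbation applied to both models
#'   (`x1(0) = x2(0)`), in deviation coordinates
#' @param ic full initial state of length `n1 + n2` (alternative to
#'   `common_ic`)
#' @param input an [input_signal()], or `NULL` for the unforced system
#' @param output output selector (rows of `y` entering the energy)
#' @param t_end integration horizon, or `"auto"`
#' @param rtol,atol integrator tolerances (lsoda)
#' @param dt reporting time step
#' @return object of class `trajectory`
#' @export
simulate_difference_system <- function(diff_system, common_ic = NULL, ic = NULL,
                                       input = NULL, output = NULL,
                                       t_end = "auto", rtol = 1e-9, atol = 1e-12,
                                       dt = 0.25) {
  ds <- diff_system
  rows <- output_rows(ds, output)
  if (!is.null(common_ic)) {
    if (ds$n1 != ds$n2) stop(validation_error("common_ic requires n1 == n2"))
    ic <- c(common_ic, common_ic)
  }
  if (is.null(ic)) ic <- rep(0, ds$n1 + ds$n2)
  stopifnot(length(ic) == ds$n1 + ds$n2)

  rhs <- .diff_rhs(ds, input)
  T_active <- if (is.null(input)) 0 else input$T_active
  slow <- max(Re(c(ds$m1$eigenvalues, ds$m2$eigenvalues)))
  if (!identical(t_end, "auto")) {
    Tend <- t_end
  } else {
    Tend <- T_active + 10 / abs(slow)
  }
  Ptail <- .tail_gramian(ds, rows)

  integrate_to <- function(Tend) {
    legs <- unique(c(0, min(T_active, Tend), Tend))
    y0 <- c(ic, 0)
    pieces <- list()
    for (i in seq_len(length(legs) - 1)) {
      tt <- seq(legs[i], legs[i + 1], by = dt)
      if (tt[length(tt)] < legs[i + 1]) tt <- c(tt, legs[i + 1])
      hmax <- if (!is.null(input) && input$kind == "square" && legs[i] < T_active)
        min(pi / input$omega / 4, 1) else NULL
      args <- list(y = y0, times = tt, func = rhs, parms = list(rows = rows),
                   method = "lsoda", rtol = rtol, atol = atol)
      if (!is.null(hmax)) args$hmax <- hmax
      out <- do.call(deSolve::ode, args)
      if (attr(out, "istate")[1] < 0)
        stop(errorCondition("integration failure; last state recorded in the condition",
                            class = c("discrim_integration_error", "error")))
      pieces[[i]] <- out
      y0 <- as.numeric(out[nrow(out), 1 + seq_len(length(y0))])
    }
    do.call(rbind, lapply(seq_along(pieces), function(i)
      if (i == 1) pieces[[i]] else pieces[[i]][-1, , drop = FALSE]))
  }

  repeat {
    out <- integrate_to(Tend)
    xT <- as.numeric(out[nrow(out), 1 + seq_len(ds$n1 + ds$n2)])
    total <- as.numeric(out[nrow(out), 2 + ds$n1 + ds$n2])
    tail_est <- as.numeric(t(xT) %*% Ptail %*% xT)
    if (!identical(t_end, "auto")) break
    if (tail_est <= 1e-6 * max(total, 1e-300) || Tend > 1e5) break
    Tend <- Tend * 1.5
  }

  nstate <- ds$n1 + ds$n2
  times <- out[, 1]
  states <- out[, 1 + seq_len(nstate), drop = FALSE]
  colnames(states) <- ds$vars
  ycols <- grep("^ydiff", colnames(out))
  y <- out[, ycols, drop = FALSE]
  colnames(y) <- ds$output_names
  energy <- out[, 2 + nstate]
  if (any(diff(energy) < -1e-12)) energy <- cummax(energy)
  structure(list(times = times, states = states, y = y,
                 energy = energy, tail = tail_est, output = rows,
                 l2_norm = sqrt(total + tail_est),
                 tail_fraction = tail_est / max(total + tail_est, 1e-300)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory>  %d time points to t = %g;  ||y||_2 = %.6g (tail %.2g%%)\n",
              length(x$times), max(x$times), x$l2_norm, 100 * x$tail_fraction))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, which = c("difference", "energy"), ...) {
  which <- match.arg(which)
  if (which == "difference") {
    graphics::matplot(x$times, x$y, type = "l", lty = 1,
                      xlab = "time", ylab = "output difference y1 - y2", ...)
    graphics::legend("topright", colnames(x$y), col = seq_len(ncol(x$y)), lty = 1, bty = "n")
    graphics::abline(h = 0, col = "grey")
  } else {
    graphics::plot(x$times, x$energy, type = "l", xlab = "time",
                   ylab = "cumulative output energy", ...)
  }
  invisible(x)
}

#' L2 norm of a trajectory's output difference or of an input signal
#'
#' For a trajectory this is `sqrt(total energy + certified tail)`; an error is
#' raised if the tail estimate is not a small fraction of the total (the
#' asymptotic-stability assumption would be violated).
#'
#' @param x a `trajectory` or an `input_signal`
#' @return nonnegative scalar
#' @export
signal_l2_norm <- function(x) {
  if (inherits(x, "input_signal")) return(sqrt(signal_energy(x)))
  if (inherits(x, "trajectory")) {
    if (x$tail_fraction > 1e-3 && x$l2_norm > 1e-12)
      stop(errorCondition("output energy tail did not decay; asymptotic stability violated",
                          class = c("discrim_stability_error", "error")))
    return(x$l2_norm)
  }
  stop(validation_error("signal_l2_norm expects a trajectory or input_signal"))
}

# --- deterministic sphere grids --------------------------------------------

# deterministic quasi-uniform points on the unit sphere S^{d-1}
sphere_grid <- function(d, n) {
  if (n == 1) return(matrix(c(1, rep(0, d - 1)), 1))
  if (d == 1) return(matrix(c(1, -1)[seq_len(min(n, 2))], ncol = 1))
  if (d == 2) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    return(cbind(cos(th), sin(th)))
  }
  if (d == 3) {   # Fibonacci spiral
    k <- seq_len(n)
    z <- 1 - 2 * (k - 0.5) / n
    r <- sqrt(pmax(1 - z^2, 0))
    golden <- pi * (3 - sqrt(5))
    th <- golden * (k - 1)
    return(cbind(r * cos(th), r * sin(th), z))
  }
  # general d: scrambled-free Halton points mapped through the normal quantile
  H <- vapply(seq_len(d), function(j) .halton(n, .primes_list[j]), numeric(n))
  G <- stats::qnorm(pmin(pmax(H, 1e-12), 1 - 1e-12))
  G / sqrt(rowSums(G^2))
}

.primes_list <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)

.halton <- function(n, base) {
  vapply(seq_len(n), function(i) {
    f <- 1; r <- 0
    while (i > 0) { f <- f / base; r <- r + f * (i %% base); i <- i %/% base }
    r
  }, 0)
}

# --- brute-force design oracles --------------------------------------------

#' Brute-force search for the best common initial direction
#'
#' Simulates the nonlinear difference system from `beta * v` for every `v` on
#' a deterministic sphere grid, then polishes the best direction by local
#' (Nelder-Mead) search on the sphere.  This is the simulation oracle against
#' which the gramian- and storage-based designs are validated.
#'
#' @param diff_system a [concatenate_models()] result
#' @param beta perturbation magnitude
#' @param grid_size number of sphere grid points
#' @param output output selector
#' @param refine polish the best grid direction locally
#' @param rtol_search integrator tolerance during the scan (the winning value
#'   is re-simulated at `rtol_final`)
#' @return list with `direction`, `value` (simulated `||y||_2`) and the grid
#' @export
brute_force_ic_search <- function(diff_system, beta = 1, grid_size = 300,
                                  output = NULL, refine = TRUE,
                                  rtol_search = 1e-6, rtol_final = 1e-10) {
  ds <- diff_system
  if (ds$n1 != ds$n2) stop(validation_error("common-direction search requires n1 == n2"))
  if (beta <= 0) stop(validation_error("beta must be positive"))
  V <- sphere_grid(ds$n1, grid_size)
  val <- function(v, rtol) {
    tr <- simulate_difference_system(ds, common_ic = beta * v, output = output,
                                     rtol = rtol, atol = rtol * 1e-3, dt = 5)
    tr$l2_norm
  }
  vals <- apply(V, 1, val, rtol = rtol_search)
  best <- which.max(vals)
  v <- V[best, ]
  if (refine && grid_size > 1) {
    obj <- function(w) {
      nv <- sqrt(sum(w^2)); if (nv < 1e-9) return(0)
      -val(w / nv, rtol_search)
    }
    opt <- stats::optim(v, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-8, maxit = 400))
    w <- opt$par / sqrt(sum(opt$par^2))
    if (-opt$value >= vals[best]) v <- w
  }
  k <- which(abs(v) > 1e-9)[1]
  if (!is.na(k) && v[k] < 0 && ds$polynomial) {
    # keep whichever sign simulates better (the nonlinear value is not
    # sign-symmetric); try the flipped representative too
    if (val(-v, rtol_search) > val(v, rtol_search)) v <- -v
  }
  list(direction = v, value = val(v, rtol_final), beta = beta,
       grid_values = vals)
}

#' Brute-force structural search over a parameter box
#'
#' Grid search over the Cartesian product of the settable-parameter box and
#' the common initial-direction sphere, re-solving and re-shifting the steady
#' state of both models at every parameter point.  Parameter points where the
#' steady-state solve fails are skipped and recorded.
#'
#' @param model1,model2 the rival [ode_model()]s
#' @param param_box named list of intervals (defaults to the boxes declared
#'   on the models)
#' @param beta perturbation magnitude
#' @param param_grid grid points per box dimension (endpoints included)
#' @param grid_size sphere grid size per parameter point
#' @param output output selector
#' @return list with `param_point`, `direction`, `value`, the evaluation
#'   `table` and any `skipped` parameter points
#' @export
brute_force_structural_search <- function(model1, model2, param_box = NULL,
                                          beta = 1, param_grid = 5,
                                          grid_size = 60, output = NULL,
                                          rtol_search = 1e-6, rtol_final = 1e-10) {
  if (is.null(param_box)) param_box <- model1$param_boxes
  if (is.null(param_box) || length(param_box) == 0)
    stop(validation_error("param_box is empty"))
  grids <- lapply(param_box, function(iv) {
    if (iv[1] == iv[2]) iv[1] else seq(iv[1], iv[2], length.out = param_grid)
  })
  pts <- as.matrix(expand.grid(grids))
  colnames(pts) <- names(param_box)
  guess <- NULL
  best <- list(value = -Inf)
  skipped <- list()
  records <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    pp <- pts[i, ]
    ds <- tryCatch(
      difference_system(model1, model2, params1 = pp, params2 = pp,
                        guess1 = guess, guess2 = guess),
      error = function(e) e)
    if (inherits(ds, "error")) {
      skipped[[length(skipped) + 1]] <- list(param = pp, reason = conditionMessage(ds))
      next
    }
    guess <- ds$m1$x_star     # warm-start neighbouring solves
    sr <- brute_force_ic_search(ds, beta = beta, grid_size = grid_size,
                                output = output, refine = FALSE,
                                rtol_search = rtol_search, rtol_final = rtol_search)
    records[[i]] <- c(pp, value = sr$value)
    if (sr$value > best$value)
      best <- list(param = pp, direction = sr$direction, value = sr$value, ds = ds)
  }
  if (!is.finite(best$value))
    stop(errorCondition("steady-state solve failed at every grid point",
                        class = c("discrim_convergence_error", "error")))
  # polish the direction at the winning parameter point
  sr <- brute_force_ic_search(best$ds, beta = beta, grid_size = grid_size,
                              output = output, refine = TRUE,
                              rtol_search = rtol_search, rtol_final = rtol_final)
  list(param_point = best$param, direction = sr$direction, value = sr$value,
       table = do.call(rbind, Filter(Negate(is.null), records)),
       skipped = skipped)
}
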