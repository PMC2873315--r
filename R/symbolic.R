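# Rational-function helpers for the parametric steady-state shift.
#
# Structural design lets the experimenter pick parameters p in a box, and the
# steady state of each model moves with p.  For the SOS programme the shifted
# drift must be polynomial in (x, p); here the steady state is solved
# symbolically by sequential linear elimination (each equation in turn is
# linear in one remaining state), producing rational expressions whose
# denominators are later cleared against the dissipation inequality.  This
# covers the typical mass-action structure; models outside it are rejected
# with a clear error.

rat_new <- function(num, den = NULL) {
  if (is.null(den)) den <- poly_const(num$vars, 1)
  list(num = num, den = den)
}

rat_from_poly <- function(p) rat_new(p)

rat_neg <- function(a) { a$num <- poly_neg(a$num); a }

rat_add <- function(a, b) {
  rat_simplify(rat_new(poly_add(poly_mul(a$num, b$den), poly_mul(b$num, a$den)),
                       poly_mul(a$den, b$den)))
}

rat_mul <- function(a, b) {
  rat_simplify(rat_new(poly_mul(a$num, b$num), poly_mul(a$den, b$den)))
}

rat_pow <- function(a, k) {
  out <- rat_new(poly_const(a$num$vars, 1))
  while (k > 0) { out <- rat_mul(out, a); k <- k - 1 }
  out
}

rat_is_poly <- function(a) is_poly_constant(a$den)

# graded-lex leading term index of a canonical polyform
.lead_idx <- function(p) {
  deg <- rowSums(p$expo)
  cand <- which(deg == max(deg))
  cand[1]
}

# exact multivariate division: returns the quotient A / B, or NULL when the
# division is not exact
poly_div_exact <- function(A, B, max_steps = 5000L) {
  if (length(B$coef) == 0) return(NULL)
  A <- poly_canon(A); B <- poly_canon(B)
  Q <- poly_zero(A$vars)
  lb <- .lead_idx(B)
  for (step in seq_len(max_steps)) {
    if (length(A$coef) == 0) return(poly_canon(Q, drop_tol = 1e-12))
    la <- .lead_idx(A)
    qe <- A$expo[la, ] - B$expo[lb, ]
    if (any(qe < 0)) return(NULL)
    qt <- poly_monomial(A$vars, qe, A$coef[la] / B$coef[lb])
    Q <- poly_add(Q, qt)
    A <- poly_canon(poly_sub(A, poly_mul(qt, B)), drop_tol = 1e-12)
  }
  NULL
}

# cancel the denominator when it divides the numerator exactly; normalize the
# denominator to unit leading coefficient
rat_simplify <- function(a) {
  a$num <- poly_canon(a$num, drop_tol = 1e-14)
  a$den <- poly_canon(a$den, drop_tol = 1e-14)
  if (is_poly_constant(a$den)) {
    d <- poly_constant_value(a$den)
    return(rat_new(poly_scale(a$num, 1 / d)))
  }
  q <- poly_div_exact(a$num, a$den)
  if (!is.null(q)) return(rat_new(q))
  lc <- a$den$coef[.lead_idx(a$den)]
  a$num <- poly_scale(a$num, 1 / lc)
  a$den <- poly_scale(a$den, 1 / lc)
  a
}

rat_eval <- function(a, point) poly_eval(a$num, point) / poly_eval(a$den, point)

# substitute rational expressions for a subset of variables in a polynomial
rat_substitute <- function(p, subs) {
  vars <- p$vars
  out <- rat_new(poly_zero(vars))
  snames <- names(subs)
  for (t in seq_along(p$coef)) {
    e <- p$expo[t, ]
    rest <- e; rest[match(snames, vars)] <- 0
    term <- rat_new(poly_monomial(vars, rest, p$coef[t]))
    for (s in snames) {
      k <- e[match(s, vars)]
      if (k > 0) term <- rat_mul(term, rat_pow(subs[[s]], k))
    }
    out <- rat_add(out, term)
  }
  out
}

# --- symbolic steady state --------------------------------------------------

#' Solve a model's steady state symbolically in the settable parameters
#'
#' Sequentially eliminates states from `f(x) + g(x) u0 = 0`: at every pass
#' one equation that is linear in one remaining state (after substituting the
#' states already solved) is solved for it.  The result expresses each
#' steady-state component as a rational function of the free parameters.
#'
#' @param model a polynomial [ode_model()]
#' @param free_params names of the parameters kept symbolic
#' @return named list of rational expressions (num/den polyforms over the
#'   model states and free parameters; only the parameters occur)
#' @keywords internal
symbolic_steady_state <- function(model, free_params) {
  if (!model$polynomial)
    stop(validation_error("symbolic steady state requires a polynomial model"))
  vars <- c(model$states, free_params)
  consts <- model$params[setdiff(names(model$params), free_params)]
  Fp <- lapply(seq_len(model$n), function(i) {
    p <- poly_parse(model$drift[i], vars, consts)
    if (model$q > 0)
      for (k in seq_len(model$q))
        p <- poly_add(p, poly_scale(poly_parse(model$input_map[i, k], vars, consts),
                                    model$basal_input[k]))
    p
  })
  solved <- list()
  eqs <- seq_len(model$n)
  states_left <- model$states
  progress <- TRUE
  while (length(states_left) && progress) {
    progress <- FALSE
    for (i in eqs) {
      Fsub <- rat_substitute(Fp[[i]], solved)
      num <- Fsub$num
      for (s in states_left) {
        js <- match(s, vars)
        others <- match(setdiff(states_left, s), vars)
        if (length(num$coef) == 0) next
        if (poly_degree_in(num, s) != 1) next
        if (length(others) && any(num$expo[, others] > 0)) next
        sel <- num$expo[, js] == 1
        c1 <- num; c1$expo <- num$expo[sel, , drop = FALSE]; c1$coef <- num$coef[sel]
        c1$expo[, js] <- 0
        c0 <- num; c0$expo <- num$expo[!sel, , drop = FALSE]; c0$coef <- num$coef[!sel]
        solved[[s]] <- rat_simplify(rat_new(poly_neg(poly_canon(c0)), poly_canon(c1)))
        states_left <- setdiff(states_left, s)
        eqs <- setdiff(eqs, i)
        progress <- TRUE
        break
      }
      if (progress) break
    }
  }
  if (length(states_left))
    stop(errorCondition(paste0(
      "steady state is not solvable by sequential linear elimination (stuck on ",
      paste(states_left, collapse = ", "),
      "); structural design needs a polynomial parameter dependence"),
      class = c("discrim_symbolic_error", "error")))
  solved[model$states]
}

# deviation drift of one model as rational functions of (deviation states,
# free parameters): f(x~ + x*(p)) + g(x~ + x*(p)) u0, with x* the symbolic
# steady state
symbolic_shifted_drift <- function(model, free_params, sstate = NULL) {
  vars <- c(model$states, free_params)
  consts <- model$params[setdiff(names(model$params), free_params)]
  if (is.null(sstate)) sstate <- symbolic_steady_state(model, free_params)
  subs <- lapply(model$states, function(s) {
    r <- sstate[[s]]
    rat_new(poly_add(poly_mul(poly_var(vars, s), r$den), r$num), r$den)
  })
  names(subs) <- model$states
  lapply(seq_len(model$n), function(i) {
    p <- poly_parse(model$drift[i], vars, consts)
    if (model$q > 0)
      for (k in seq_len(model$q))
        p <- poly_add(p, poly_scale(poly_parse(model$input_map[i, k], vars, consts),
                                    model$basal_input[k]))
    rat_simplify(rat_substitute(p, subs))
  })
}
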