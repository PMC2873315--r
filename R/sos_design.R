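# SOS design programmes: storage functions for initial-condition design,
# L2-gain upper bounds for input design, parametric storage for structural
# design, and optimizer extraction from dual moments.
#
# All programmes are assembled in rescaled coordinates: deviation states are
# divided by the region radius alpha (so the analysis region is the unit
# ball) and box parameters are mapped affinely to [-1, 1]; certificates are
# mapped back symbolically before they are returned.

# scaled polynomial data of a difference system
.sos_system <- function(ds, alpha, with_input = FALSE) {
  if (!ds$polynomial)
    stop(validation_error(
      "the SOS engine requires polynomial vector fields; this model pair is flagged rational (linear/simulation methods remain available)"))
  xv <- ds$vars
  uv <- if (with_input) paste0("u", seq_len(ds$q)) else character(0)
  vars <- c(xv, uv)
  sc <- stats::setNames(rep(alpha, length(xv)), xv)
  lift <- function(p) poly_extend_vars(p, vars)
  clean <- function(p) poly_canon(p, drop_tol = 1e-12 * max(abs(p$coef), 1e-300))
  f <- lapply(ds$drift, function(p)
    clean(poly_scale(poly_subst_affine(lift(p), scale = sc), 1 / alpha)))
  names(f) <- xv
  h <- lapply(ds$output, function(p) clean(poly_subst_affine(lift(p), scale = sc)))
  # the input is rescaled along with the states (u = alpha * u-hat), which
  # keeps the input-map coefficients O(1); the gain level is mapped back by
  # 1/alpha^2 afterwards
  g <- NULL
  if (with_input && ds$q > 0) {
    g <- matrix(vector("list", length(xv) * ds$q), length(xv), ds$q)
    for (k in seq_len(ds$q)) for (i in seq_len(ds$n1 + ds$n2))
      g[[i, k]] <- clean(poly_subst_affine(lift(ds$input_map[[i, k]]), scale = sc))
  }
  ball <- function(idx) {
    out <- poly_const(vars, 1)
    for (v in xv[idx]) out <- poly_sub(out, poly_pow(poly_var(vars, v), 2))
    out
  }
  list(vars = vars, xv = xv, uv = uv, f = f, h = h, g = g,
       region1 = ball(seq_len(ds$n1)), region2 = ball(ds$n1 + seq_len(ds$n2)))
}

# monomial basis (exponent matrix) with per-group degree caps
.capped_monomials <- function(nv, caps) {
  M <- monomials_upto(nv, caps$total)
  keep <- rep(TRUE, nrow(M))
  for (g in caps$groups)
    keep <- keep & rowSums(M[, g$idx, drop = FALSE]) <= g$cap
  M[keep, , drop = FALSE]
}

.accept_solution <- function(sol, what) {
  if (sol$status == "optimal") return(invisible())
  if (sol$status == "infeasible")
    stop(errorCondition(paste0(what, ": SOS programme infeasible at the requested degrees; try increasing deg_S"),
                        class = c("discrim_infeasible_error", "error")))
  if (sol$status == "max_iter" &&
      max(sol$sdp$pres, sol$sdp$dres, sol$sdp$gap, na.rm = TRUE) < 5e-4) {
    warning(what, ": solver stopped at iteration cap with residuals ",
            format(max(sol$sdp$pres, sol$sdp$dres), digits = 2),
            "; certificate is approximate")
    return(invisible())
  }
  stop(errorCondition(paste0(what, ": SDP solver failed (status ", sol$status, ")"),
                      class = c("discrim_solver_error", "error")))
}

# unscale a polynomial in x-hat coordinates back to deviation coordinates
.unscale_x <- function(p, xv, alpha) {
  poly_subst_affine(p, scale = stats::setNames(rep(1 / alpha, length(xv)), xv))
}

#' Storage-function certificate for initial-condition design
#'
#' Searches for an SOS storage function `S` with `S(0) = 0` such that
#' `-dS/dt - y'y >= 0` on the region `D = {|x1| <= alpha, |x2| <= alpha}`
#' (certified with SOS multipliers on the two ball constraints).  Integrating
#' the dissipation inequality gives the output-energy bound
#' `||y||_2^2 <= S(x(0))` for trajectories starting inside the certified
#' level set.  Among all feasible storage functions the programme minimizes
#' the trace of the quadratic part of `S` at the origin, so level sets are as
#' large as possible; for a linear system this recovers the observability
#' gramian exactly.
#'
#' @param diff_system a polynomial [concatenate_models()] result
#' @param alpha region radius in state units (`0.1` matches the physical
#'   bound on the response-regulator coordinate in the chemotaxis case study)
#' @param deg_S degree of the storage function (even, >= 2)
#' @param deg_sigma degree of the region multipliers
#' @param tol,max_iter SDP solver controls
#' @return object of class `storage_certificate`
#' @export
storage_for_ic_design <- function(diff_system, alpha = 0.1, deg_S = 2,
                                  deg_sigma = 2, tol = 1e-6, max_iter = 40000L,
                                  verbose = FALSE) {
  ds <- diff_system
  if (alpha <= 0) stop(validation_error("alpha must be positive"))
  if (deg_S %% 2 != 0 || deg_S < 2) stop(validation_error("deg_S must be even and >= 2"))
  sys <- .sos_system(ds, alpha, with_input = FALSE)
  nv <- length(sys$vars)
  prog <- sos_program(sys$vars)

  degf <- max(vapply(sys$f, poly_degree, 0))
  degh <- max(vapply(sys$h, poly_degree, 0))
  maxdeg <- max(deg_S - 1 + degf, 2 * degh, deg_sigma + 2)

  # the whole dissipation identity vanishes on the subspace x = 0, so every
  # block basis excludes x-free monomials (facial reduction: their Gram
  # diagonals would be forced to zero and stall the solver)
  sp_add_gram(prog, "S", monomials_upto(nv, deg_S / 2, dmin = 1))
  n1 <- ds$n1
  basis_sig <- function(idx) {
    M <- monomials_upto(nv, max(deg_sigma / 2, 1), dmin = 1)
    other <- setdiff(seq_len(nv), idx)
    M[rowSums(M[, other, drop = FALSE]) == 0, , drop = FALSE]
  }
  sp_add_gram(prog, "sig1", basis_sig(seq_len(n1)))
  sp_add_gram(prog, "sig2", basis_sig(n1 + seq_len(ds$n2)))

  sp_add_gram_lie(prog, "S", sys$f, sign = -1)
  for (hj in sys$h) sp_add_poly(prog, poly_mul(hj, hj), NA_integer_, scale = -1)
  sp_add_gram_poly(prog, "sig1", factor = sys$region1, sign = -1)
  sp_add_gram_poly(prog, "sig2", factor = sys$region2, sign = -1)
  sp_add_pruned_gram(prog, "Q0", monomials_upto(nv, ceiling(maxdeg / 2), dmin = 1))
  sp_add_gram_poly(prog, "Q0", sign = -1)
  sp_objective_trace_quadratic(prog, "S", weight = 1)

  sol <- sp_solve(prog, tol = tol, max_iter = max_iter, verbose = verbose)
  .accept_solution(sol, "storage_for_ic_design")

  S_scaled <- gram_polynomial(prog, "S", sol$grams$S)
  sig1 <- gram_polynomial(prog, "sig1", sol$grams$sig1)
  sig2 <- gram_polynomial(prog, "sig2", sol$grams$sig2)
  # independent identity re-check: residual of the assembled constraint
  lieS <- poly_zero(sys$vars)
  for (vn in names(sys$f))
    lieS <- poly_add(lieS, poly_mul(poly_diff(S_scaled, vn), sys$f[[vn]]))
  target <- poly_neg(lieS)
  for (hj in sys$h) target <- poly_sub(target, poly_mul(hj, hj))
  target <- poly_sub(target, poly_mul(sig1, sys$region1))
  target <- poly_sub(target, poly_mul(sig2, sys$region2))
  resid <- poly_canon(poly_sub(target, gram_polynomial(prog, "Q0", sol$grams$Q0)),
                      drop_tol = 1e-12)
  ver <- sos_verify(prog, sol, resid)

  structure(list(kind = "ic", S = .unscale_x(S_scaled, sys$xv, alpha),
                 S_scaled = S_scaled, sigma1 = sig1, sigma2 = sig2,
                 alpha = alpha, deg_S = deg_S, deg_sigma = deg_sigma,
                 vars = ds$vars, n1 = ds$n1, n2 = ds$n2,
                 trace_objective = sol$objective,
                 grams = sol$grams, verification = ver,
                 solver = sol$sdp[c("status", "iters", "pres", "dres", "gap")]),
            class = "storage_certificate")
}

#' @export
print.storage_certificate <- function(x, ...) {
  cat(sprintf("<storage_certificate (%s)>  deg(S) = %d, region radius alpha = %g\n",
              x$kind, x$deg_S, x$alpha))
  cat(sprintf("  solver %s (%d iters), identity residual %.2e, min Gram eig %.2e\n",
              x$solver$status, x$solver$iters, x$verification$residual,
              min(x$verification$min_eig)))
  invisible(x)
}

# --- optimizer extraction ---------------------------------------------------

# common-initial-state restriction of a storage polynomial: substitute
# x1_i = x2_i = v_i (and keep any trailing parameter variables)
.common_restriction <- function(S, n, extra_vars = character(0)) {
  vnames <- paste0("v", seq_len(n))
  newvars <- c(vnames, extra_vars)
  expo <- matrix(0, nrow(S$expo), length(newvars))
  expo[, seq_len(n)] <- S$expo[, seq_len(n), drop = FALSE] +
    S$expo[, n + seq_len(n), drop = FALSE]
  if (length(extra_vars))
    expo[, n + seq_along(extra_vars)] <-
      S$expo[, 2 * n + seq_along(extra_vars), drop = FALSE]
  poly_canon(new_polyform(newvars, expo, S$coef))
}

# moment-based minimizer extraction for programmes of the form
#   min gamma  s.t.  gamma - F(w) - multipliers  is SOS :
# the equality duals form a moment sequence concentrated on the maximizer set
.extract_moments <- function(sol, nv_total, v_idx, t_idx = integer(0),
                             rank_tol = 1e-3) {
  y0 <- moment_of(sol, rep(0, nv_total))
  if (is.na(y0) || abs(y0) < 1e-9)
    return(list(ok = FALSE, reason = "vanishing zeroth moment"))
  mom <- function(expo) moment_of(sol, expo) / y0
  # second-order moment block in the v variables (the objective is even in v,
  # so first moments vanish by symmetry and the direction lives in E[v v'])
  k <- length(v_idx)
  M1 <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    e <- rep(0, nv_total); e[v_idx[i]] <- e[v_idx[i]] + 1; e[v_idx[j]] <- e[v_idx[j]] + 1
    M1[i, j] <- M1[j, i] <- mom(e)
  }
  if (anyNA(M1)) return(list(ok = FALSE, reason = "missing moments"))
  ev <- eigen((M1 + t(M1)) / 2, symmetric = TRUE)
  ratio <- if (ev$values[1] <= 0) Inf else max(ev$values[-1], 0) / ev$values[1]
  v <- ev$vectors[, 1]
  kk <- which(abs(v) > 1e-9)[1]
  if (!is.na(kk) && v[kk] < 0) v <- -v
  tval <- vapply(t_idx, function(ti) {
    e <- rep(0, nv_total); e[ti] <- 1; mom(e)
  }, 0)
  list(ok = ev$values[1] > 0, direction = v, rank_ratio = ratio,
       t = tval, M1 = M1)
}

#' Extract the optimal common initial direction from a storage certificate
#'
#' Shrinks the level set of the common-initial-state restriction of `S` until
#' it touches the sphere of radius `beta`: the touching point maximizes the
#' storage-based output-energy bound and is recovered from the dual moment
#' matrix of the level-set programme, with a multi-start search on the sphere
#' as fallback.
#'
#' @param certificate a [storage_for_ic_design()] result
#' @param beta common perturbation magnitude (`|x1(0)| = |x2(0)| = beta`)
#' @param rank_tol second-eigenvalue ratio below which the dual moment block
#'   counts as rank one
#' @param agree_tol relative disagreement between the dual value and the
#'   fallback search above which extraction is declared failed
#' @return list with the unit `direction`, `xhat = beta * direction`, the
#'   certified `energy_bound` (level value, bounds `||y||_2^2`), `route`
#'   (`"dual_moment"` or `"fallback_search"`) and diagnostics
#' @export
extract_optimal_ic <- function(certificate, beta = 1, rank_tol = 1e-3,
                               agree_tol = 0.05, tol = 1e-7) {
  n <- certificate$n1
  if (beta < 0) stop(validation_error("beta must be nonnegative"))
  if (beta == 0)
    return(list(direction = rep(0, n), xhat = rep(0, n), energy_bound = 0,
                route = "trivial", rank_ratio = NA_real_))
  if (beta > certificate$alpha && isTRUE(certificate$enforce_containment))
    stop(validation_error("beta exceeds the certified region radius alpha"))
  Sc <- .common_restriction(certificate$S, n)
  res <- .maximize_even_poly_on_sphere(Sc, n, beta, rank_tol = rank_tol,
                                       agree_tol = agree_tol, tol = tol)
  list(direction = res$direction, xhat = beta * res$direction,
       energy_bound = res$value, l2_bound = sqrt(max(res$value, 0)),
       route = res$route, rank_ratio = res$rank_ratio,
       dual_value = res$dual_value, fallback_value = res$fallback_value)
}

# shared worker: maximize an even polynomial over the sphere |v| = beta via
# the SOS level-set programme with dual-moment extraction + local fallback
.maximize_even_poly_on_sphere <- function(Sc, n, beta, rank_tol = 1e-3,
                                          agree_tol = 0.05, tol = 1e-7) {
  vnames <- Sc$vars
  degS <- poly_degree(Sc)
  prog <- sos_program(vnames)
  gcol <- sp_add_free(prog, "gamma")
  lam_expos <- monomials_upto(n, max(degS - 2, 0))
  lam_cols <- vapply(seq_len(nrow(lam_expos)), function(i)
    sp_add_free(prog, paste0("lam", i)), 0)

  sphere <- poly_const(vnames, beta^2)
  for (v in vnames) sphere <- poly_sub(sphere, poly_pow(poly_var(vnames, v), 2))
  sp_add_chunk(prog, matrix(0, 1, n), 1, gcol)                  # + gamma
  sp_add_poly(prog, Sc, NA_integer_, scale = -1)                # - S~(v)
  for (i in seq_len(nrow(lam_expos))) {                         # - lam(v) (b^2 - |v|^2)
    lp <- poly_mul(poly_monomial(vnames, lam_expos[i, ]), sphere)
    sp_add_poly(prog, lp, lam_cols[i], scale = -1)
  }
  sp_add_pruned_gram(prog, "Q0", monomials_upto(n, ceiling(degS / 2)))
  sp_add_gram_poly(prog, "Q0", sign = -1)
  sp_objective(prog, gcol, 1)
  sol <- sp_solve(prog, tol = tol)
  .accept_solution(sol, "optimizer extraction")
  gamma <- sol$free[["gamma"]]

  ext <- .extract_moments(sol, n, seq_len(n), rank_tol = rank_tol)
  eval_S <- function(v) poly_eval(Sc, stats::setNames(v, vnames))
  # multi-start local search fallback / cross-check
  starts <- sphere_grid(n, 24)
  best_fb <- -Inf; v_fb <- starts[1, ]
  for (i in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[i, ], function(w) {
      nw <- sqrt(sum(w^2)); if (nw < 1e-9) return(0)
      -eval_S(beta * w / nw)
    }, method = "Nelder-Mead", control = list(reltol = 1e-10, maxit = 500))
    if (-opt$value > best_fb) { best_fb <- -opt$value; v_fb <- opt$par / sqrt(sum(opt$par^2)) }
  }
  kk <- which(abs(v_fb) > 1e-9)[1]
  if (!is.na(kk) && v_fb[kk] < 0) v_fb <- -v_fb

  dual_ok <- isTRUE(ext$ok) && ext$rank_ratio < rank_tol &&
    abs(eval_S(beta * ext$direction) - gamma) <= agree_tol * max(abs(gamma), 1e-9)
  fb_ok <- abs(best_fb - gamma) <= agree_tol * max(abs(gamma), 1e-9)
  if (dual_ok) {
    list(direction = ext$direction, value = gamma, route = "dual_moment",
         rank_ratio = ext$rank_ratio, dual_value = gamma, fallback_value = best_fb)
  } else if (fb_ok) {
    list(direction = v_fb, value = best_fb, route = "fallback_search",
         rank_ratio = if (is.null(ext$rank_ratio)) NA_real_ else ext$rank_ratio,
         dual_value = gamma, fallback_value = best_fb)
  } else {
    stop(errorCondition(sprintf(
      "extraction failed: dual level %.6g vs fallback maximum %.6g disagree by more than %.0f%%",
      gamma, best_fb, 100 * agree_tol),
      class = c("discrim_extraction_error", "error")))
  }
}

# --- L2-gain bound ----------------------------------------------------------

#' SOS upper bound on the L2-gain of the nonlinear difference system
#'
#' Searches for a storage function `S` and level `g` such that
#' `-dS/dt - y'y + g u'u >= 0` on the region `D` (SOS-certified with ball
#' multipliers).  Integrating from the steady state gives
#' `||y||_2^2 <= g ||u||_2^2` for trajectories that remain in `D`, so
#' `sqrt(g)` bounds the output-difference norm achievable by any unit-energy
#' stimulus.  The level enters the SDP linearly and is minimized directly.
#'
#' @inheritParams storage_for_ic_design
#' @return object of class `gain_certificate`; the reported `gain` is
#'   `sqrt(g)`, on the same scale as the linearized Bode peak
#' @export
l2_gain_bound <- function(diff_system, alpha = 0.1, deg_S = 2, deg_sigma = 2,
                          tol = 5e-6, max_iter = 60000L, verbose = FALSE) {
  ds <- diff_system
  if (ds$q < 1) stop(validation_error("gain bound requires at least one input"))
  if (alpha <= 0) stop(validation_error("alpha must be positive"))
  sys <- .sos_system(ds, alpha, with_input = TRUE)
  nv <- length(sys$vars)
  nx <- length(sys$xv)
  prog <- sos_program(sys$vars)
  gcol <- sp_add_free(prog, "gamma")

  # drift plus input terms: f_i + sum_k g_ik u_k
  fplus <- sys$f
  for (i in seq_len(nx)) for (k in seq_len(ds$q)) {
    gik <- sys$g[[i, k]]
    if (length(gik$coef))
      fplus[[i]] <- poly_add(fplus[[i]], poly_mul(gik, poly_var(sys$vars, sys$uv[k])))
  }
  degf <- max(vapply(fplus, poly_degree, 0))
  degh <- max(vapply(sys$h, poly_degree, 0))
  maxdeg <- max(deg_S - 1 + degf, 2 * degh, deg_sigma + 2, 2)

  basis_x <- function(dmax, dmin = 0) {
    M <- monomials_upto(nv, dmax, dmin = dmin)
    M[rowSums(M[, nx + seq_along(sys$uv), drop = FALSE]) == 0, , drop = FALSE]
  }
  # facial reduction as in storage_for_ic_design: no x-free basis monomials
  # in S or the region multipliers (the identity vanishes at x = 0, u = 0
  # except for the gamma u'u term, which keeps the pure-u monomial in Q0)
  sp_add_gram(prog, "S", basis_x(deg_S / 2, dmin = 1))
  sp_add_gram(prog, "sig1", basis_x(max(deg_sigma / 2, 1), dmin = 1))
  sp_add_gram(prog, "sig2", basis_x(max(deg_sigma / 2, 1), dmin = 1))

  sp_add_gram_lie(prog, "S", fplus, sign = -1)
  for (hj in sys$h) sp_add_poly(prog, poly_mul(hj, hj), NA_integer_, scale = -1)
  uu <- poly_zero(sys$vars)
  for (u in sys$uv) uu <- poly_add(uu, poly_pow(poly_var(sys$vars, u), 2))
  sp_add_poly(prog, uu, gcol, scale = 1)                        # + gamma u'u
  sp_add_gram_poly(prog, "sig1", factor = sys$region1, sign = -1)
  sp_add_gram_poly(prog, "sig2", factor = sys$region2, sign = -1)
  sp_add_pruned_gram(prog, "Q0", monomials_upto(nv, ceiling(maxdeg / 2), dmin = 1))
  sp_add_gram_poly(prog, "Q0", sign = -1)
  sp_objective(prog, gcol, 1)

  sol <- sp_solve(prog, tol = tol, max_iter = max_iter, verbose = verbose)
  .accept_solution(sol, "l2_gain_bound")
  gsq <- max(sol$free[["gamma"]], 0) / alpha^2   # undo the input rescaling

  S_scaled <- gram_polynomial(prog, "S", sol$grams$S)
  sig1 <- gram_polynomial(prog, "sig1", sol$grams$sig1)
  sig2 <- gram_polynomial(prog, "sig2", sol$grams$sig2)
  lieS <- poly_zero(sys$vars)
  for (vn in names(fplus))
    lieS <- poly_add(lieS, poly_mul(poly_diff(S_scaled, vn), fplus[[vn]]))
  target <- poly_neg(lieS)
  for (hj in sys$h) target <- poly_sub(target, poly_mul(hj, hj))
  target <- poly_add(target, poly_scale(uu, sol$free[["gamma"]]))
  target <- poly_sub(target, poly_mul(sig1, sys$region1))
  target <- poly_sub(target, poly_mul(sig2, sys$region2))
  resid <- poly_canon(poly_sub(target, gram_polynomial(prog, "Q0", sol$grams$Q0)),
                      drop_tol = 1e-12)
  ver <- sos_verify(prog, sol, resid)

  structure(list(gain = sqrt(gsq), gain_squared = gsq,
                 S = .unscale_x(S_scaled, sys$xv, alpha), S_scaled = S_scaled,
                 sigma1 = sig1, sigma2 = sig2,
                 alpha = alpha, deg_S = deg_S, deg_sigma = deg_sigma,
                 grams = sol$grams, verification = ver,
                 solver = sol$sdp[c("status", "iters", "pres", "dres", "gap")]),
            class = "gain_certificate")
}

#' @export
print.gain_certificate <- function(x, ...) {
  cat(sprintf("<gain_certificate>  L2-gain bound %.6g (level %.6g), deg(S) = %d, alpha = %g\n",
              x$gain, x$gain_squared, x$deg_S, x$alpha))
  cat(sprintf("  solver %s (%d iters), identity residual %.2e\n",
              x$solver$status, x$solver$iters, x$verification$residual))
  invisible(x)
}

# --- parametric storage for structural design -------------------------------

#' Parametric storage certificate over a settable-parameter box
#'
#' Structural design: the experimenter may fix parameters `p` anywhere in a
#' box before the experiment, and the steady state of each model moves with
#' `p`.  This programme constructs `S(x, p)`, jointly SOS in the deviation
#' states and parameters, whose dissipation inequality holds on
#' `D x Pi` (ball multipliers on the states, box multipliers
#' `(p_j - a_j)(b_j - p_j)` on the parameters).  The per-parameter
#' steady-state shift is composed symbolically; its rational denominator,
#' checked positive on the box, is cleared against the dissipation
#' inequality so the programme stays polynomial.
#'
#' @param model1,model2 polynomial rival [ode_model()]s sharing the settable
#'   parameters
#' @param param_box named list of intervals (defaults to the boxes declared
#'   on model 1)
#' @param alpha state-region radius
#' @param deg_p degree of the storage function in the parameters
#' @param tol,max_iter solver controls
#' @return a parametric `storage_certificate` (field `S` is a polynomial in
#'   the concatenated deviation states and the parameters)
#' @export
storage_structural <- function(model1, model2, param_box = NULL, alpha = 0.1,
                               deg_p = 2, tol = 2e-5, max_iter = 10000L,
                               verbose = FALSE) {
  if (is.null(param_box)) param_box <- model1$param_boxes
  if (is.null(param_box) || length(param_box) == 0)
    stop(validation_error("param_box is empty"))
  fixed <- names(param_box)[vapply(param_box, function(iv) iv[1] == iv[2], TRUE)]
  if (length(fixed) == length(param_box)) {
    pp <- vapply(param_box, `[`, 0, 1)
    ds <- difference_system(model1, model2, params1 = pp, params2 = pp)
    cert <- storage_for_ic_design(ds, alpha = alpha, tol = tol, max_iter = max_iter)
    cert$collapsed_params <- pp
    return(cert)
  }
  for (nm in fixed) {
    model1$params[[nm]] <- param_box[[nm]][1]
    model2$params[[nm]] <- param_box[[nm]][1]
    param_box[[nm]] <- NULL
  }
  pnames <- names(param_box)
  if (!model1$polynomial || !model2$polynomial)
    stop(validation_error("structural SOS design requires polynomial models"))

  ss1 <- symbolic_steady_state(model1, pnames)
  ss2 <- symbolic_steady_state(model2, pnames)
  # validate the symbolic shift against the numeric solver on a box grid
  gridpts <- as.matrix(expand.grid(lapply(param_box, function(iv)
    seq(iv[1], iv[2], length.out = 3))))
  colnames(gridpts) <- pnames
  for (r in seq_len(nrow(gridpts))) {
    pp <- gridpts[r, ]
    for (mi in 1:2) {
      mod <- if (mi == 1) model1 else model2
      ssy <- if (mi == 1) ss1 else ss2
      num <- compute_steady_state(mod, params = pp,
                                  guess = vapply(mod$states, function(s)
                                    rat_eval(ssy[[s]], c(pp, stats::setNames(rep(0, mod$n), mod$states))), 0))
      sym <- vapply(mod$states, function(s)
        rat_eval(ssy[[s]], c(pp, stats::setNames(rep(0, mod$n), mod$states))), 0)
      if (max(abs(sym - num$x_star)) > 1e-8)
        stop(errorCondition("symbolic steady-state shift disagrees with the numeric solve beyond 1e-8",
                            class = c("discrim_symbolic_error", "error")))
    }
  }

  d1 <- symbolic_shifted_drift(model1, pnames, ss1)
  d2 <- symbolic_shifted_drift(model2, pnames, ss2)
  # deviation outputs h(x~ + x*) - h(x*): must be polynomial in (x~, p)
  hdev <- function(model, ssy) {
    vars <- c(model$states, pnames)
    consts <- model$params[setdiff(names(model$params), pnames)]
    subs_full <- lapply(model$states, function(s) {
      r <- ssy[[s]]
      rat_new(poly_add(poly_mul(poly_var(vars, s), r$den), r$num), r$den)
    })
    names(subs_full) <- model$states
    lapply(model$output_map, function(ex) {
      hp <- poly_parse(ex, vars, consts)
      a <- rat_substitute(hp, subs_full)
      b <- rat_substitute(hp, ssy)
      d <- rat_simplify(rat_add(a, rat_neg(b)))
      if (!rat_is_poly(d))
        stop(validation_error("structural design requires outputs whose deviation is polynomial in the parameters"))
      d$num
    })
  }
  h1 <- hdev(model1, ss1); h2 <- hdev(model2, ss2)

  n1 <- model1$n; n2 <- model2$n
  xv <- c(paste0(model1$states, "_m1"), paste0(model2$states, "_m2"))
  vars <- c(xv, pnames)
  relift <- function(p, which) {
    pv <- p
    pv$vars <- c(paste0((if (which == 1) model1 else model2)$states,
                        if (which == 1) "_m1" else "_m2"), pnames)
    poly_extend_vars(pv, vars)
  }
  nums <- c(lapply(d1, function(r) relift(r$num, 1)),
            lapply(d2, function(r) relift(r$num, 2)))
  dens <- c(lapply(d1, function(r) relift(r$den, 1)),
            lapply(d2, function(r) relift(r$den, 2)))
  y <- lapply(seq_along(h1), function(i)
    poly_sub(relift(h1[[i]], 1), relift(h2[[i]], 2)))

  # common cleared denominator D(p) = product of the distinct denominators
  keys <- vapply(dens, function(d) paste(format(d, digits = 12), collapse = ""), "")
  nonconst <- !vapply(dens, is_poly_constant, TRUE)
  uniq <- !duplicated(keys) & nonconst
  D <- poly_const(vars, 1)
  for (i in which(uniq)) D <- poly_mul(D, dens[[i]])
  f_clear <- lapply(seq_along(nums), function(i) {
    Mi <- if (is_poly_constant(dens[[i]]))
      poly_scale(D, 1 / poly_constant_value(dens[[i]]))
    else poly_div_exact(D, dens[[i]])
    if (is.null(Mi))
      stop(errorCondition("could not clear the steady-state denominators",
                          class = c("discrim_symbolic_error", "error")))
    poly_mul(nums[[i]], Mi)
  })
  # D must be positive on the box (sign-definite denominator)
  chk <- as.matrix(expand.grid(lapply(param_box, function(iv)
    seq(iv[1], iv[2], length.out = 7))))
  colnames(chk) <- pnames
  Dvals <- apply(chk, 1, function(pp)
    poly_eval(D, c(stats::setNames(rep(0, n1 + n2), xv), pp)))
  if (any(Dvals <= 0))
    stop(errorCondition("cleared denominator changes sign on the parameter box",
                        class = c("discrim_symbolic_error", "error")))

  # rescale: x = alpha * xhat, p_j = mid_j + wid_j * t_j  (box -> [-1,1])
  mid <- vapply(param_box, function(iv) mean(iv), 0)
  wid <- vapply(param_box, function(iv) diff(iv) / 2, 0)
  shift <- stats::setNames(mid, pnames)
  scalev <- c(stats::setNames(rep(alpha, n1 + n2), xv), stats::setNames(wid, pnames))
  resc <- function(p) poly_subst_affine(p, shift = shift, scale = scalev)
  f_s <- lapply(f_clear, function(p) poly_scale(resc(p), 1 / alpha))
  names(f_s) <- xv
  y_s <- lapply(y, resc)
  D_s <- resc(D)

  np <- length(pnames)
  nv <- length(vars)
  xidx <- seq_len(n1 + n2); pidx <- n1 + n2 + seq_len(np)
  prog <- sos_program(vars)

  # S basis: linear in the states times parameter monomials up to deg_p/2
  basisS <- {
    Mp <- monomials_upto(np, max(deg_p / 2, 0))
    do.call(rbind, lapply(xidx, function(i) {
      out <- matrix(0, nrow(Mp), nv)
      out[, i] <- 1
      out[, pidx] <- Mp
      out
    }))
  }
  # every block basis carries at least one state factor: the dissipation
  # identity vanishes identically on x = 0 (facial reduction)
  basis_x1p <- {
    M <- monomials_upto(nv, 2, dmin = 1)
    M[rowSums(M[, xidx, drop = FALSE]) == 1 &
        rowSums(M[, pidx, drop = FALSE]) <= 1, , drop = FALSE]
  }
  sp_add_gram(prog, "S", basisS)
  sp_add_gram(prog, "sig1", basis_x1p)
  sp_add_gram(prog, "sig2", basis_x1p)
  for (j in seq_len(np)) sp_add_gram(prog, paste0("box", j), basis_x1p)

  ball <- function(idx) {
    out <- poly_const(vars, 1)
    for (v in xv[idx]) out <- poly_sub(out, poly_pow(poly_var(vars, v), 2))
    out
  }
  reg1 <- ball(seq_len(n1)); reg2 <- ball(n1 + seq_len(n2))
  boxpoly <- lapply(seq_len(np), function(j)
    poly_sub(poly_const(vars, 1), poly_pow(poly_var(vars, pnames[j]), 2)))

  # degree caps for the main Gram block, from the actual constraint support
  degx <- function(p) if (length(p$coef) == 0) 0 else max(rowSums(p$expo[, xidx, drop = FALSE]))
  degp <- function(p) if (length(p$coef) == 0) 0 else max(rowSums(p$expo[, pidx, drop = FALSE]))
  supp_polys <- c(
    list(D_s),
    lapply(seq_along(y_s), function(i) poly_mul(D_s, poly_mul(y_s[[i]], y_s[[i]]))),
    lapply(seq_along(f_s), function(i) f_s[[i]]),
    list(reg1, boxpoly[[1]])
  )
  mx <- max(vapply(supp_polys, degx, 0)) + 1 + 0   # +1: dS/dx has x-degree 1
  mp <- max(vapply(supp_polys, degp, 0)) + deg_p
  mt <- max(vapply(supp_polys, function(p) poly_degree(p), 0)) + deg_p + 1
  mt <- max(mt, 4); mx <- max(mx, 4); mp <- max(mp, 2 + 2 * 1)
  caps <- list(total = ceiling(mt / 2),
               groups = list(list(idx = xidx, cap = ceiling(mx / 2)),
                             list(idx = pidx, cap = ceiling(mp / 2))))

  sp_add_gram_lie(prog, "S", f_s, sign = -1)
  for (yj in y_s) sp_add_poly(prog, poly_mul(D_s, poly_mul(yj, yj)), NA_integer_, scale = -1)
  sp_add_gram_poly(prog, "sig1", factor = reg1, sign = -1)
  sp_add_gram_poly(prog, "sig2", factor = reg2, sign = -1)
  for (j in seq_len(np))
    sp_add_gram_poly(prog, paste0("box", j), factor = boxpoly[[j]], sign = -1)
  cand <- .capped_monomials(nv, caps)
  cand <- cand[rowSums(cand[, xidx, drop = FALSE]) >= 1, , drop = FALSE]
  sp_add_pruned_gram(prog, "Q0", cand)
  sp_add_gram_poly(prog, "Q0", sign = -1)
  sp_objective_gram_trace(prog, "S")

  sol <- sp_solve(prog, tol = tol, max_iter = max_iter, verbose = verbose)
  .accept_solution(sol, "storage_structural")

  S_scaled <- gram_polynomial(prog, "S", sol$grams$S)
  # unscale back to deviation states and raw parameters
  S_un <- poly_subst_affine(S_scaled,
                            shift = stats::setNames(-mid / wid, pnames),
                            scale = c(stats::setNames(rep(1 / alpha, n1 + n2), xv),
                                      stats::setNames(1 / wid, pnames)))
  lieS <- poly_zero(vars)
  for (vn in names(f_s))
    lieS <- poly_add(lieS, poly_mul(poly_diff(S_scaled, vn), f_s[[vn]]))
  target <- poly_neg(lieS)
  for (yj in y_s) target <- poly_sub(target, poly_mul(D_s, poly_mul(yj, yj)))
  target <- poly_sub(target, poly_mul(gram_polynomial(prog, "sig1", sol$grams$sig1), reg1))
  target <- poly_sub(target, poly_mul(gram_polynomial(prog, "sig2", sol$grams$sig2), reg2))
  for (j in seq_len(np))
    target <- poly_sub(target, poly_mul(gram_polynomial(prog, paste0("box", j), sol$grams[[paste0("box", j)]]),
                                        boxpoly[[j]]))
  resid <- poly_canon(poly_sub(target, gram_polynomial(prog, "Q0", sol$grams$Q0)),
                      drop_tol = 1e-12)
  ver <- sos_verify(prog, sol, resid)

  structure(list(kind = "structural", S = S_un, S_scaled = S_scaled,
                 alpha = alpha, deg_S = 2, deg_p = deg_p,
                 param_box = param_box, param_names = pnames,
                 param_mid = mid, param_wid = wid,
                 denominator = D, vars = xv, n1 = n1, n2 = n2,
                 grams = sol$grams, verification = ver,
                 trace_objective = sol$objective,
                 solver = sol$sdp[c("status", "iters", "pres", "dres", "gap")]),
            class = "storage_certificate")
}

#' Extract the optimal parameter point and initial direction
#'
#' Level-set extraction for the parametric certificate: maximizes
#' `S((v, v), p)` over the sphere `|v| = beta` and the parameter box, reading
#' the maximizer off the dual moment sequence (direction from the
#' second-order moment block, parameters from the first-order moments), with
#' a multi-start box-constrained search as fallback.
#'
#' @param certificate a parametric [storage_structural()] certificate
#' @param beta common perturbation magnitude
#' @param rank_tol,agree_tol as in [extract_optimal_ic()]
#' @return list with `param_point`, unit `direction`, `energy_bound`,
#'   `route` and diagnostics
#' @export
extract_structural_optimum <- function(certificate, beta = 1, rank_tol = 1e-3,
                                       agree_tol = 0.05, tol = 1e-7) {
  if (certificate$kind != "structural") {
    ext <- extract_optimal_ic(certificate, beta = beta, rank_tol = rank_tol,
                              agree_tol = agree_tol, tol = tol)
    ext$param_point <- certificate$collapsed_params
    return(ext)
  }
  n <- certificate$n1
  pn <- certificate$param_names
  np <- length(pn)
  mid <- certificate$param_mid; wid <- certificate$param_wid
  # common restriction, with parameters mapped to t in [-1, 1]
  Sc <- .common_restriction(certificate$S, n, extra_vars = pn)
  Sc <- poly_subst_affine(Sc, shift = stats::setNames(mid, pn),
                          scale = stats::setNames(wid, pn))
  vnames <- Sc$vars
  nv <- n + np
  degv <- 2; degt <- poly_degree_in(Sc, pn)

  prog <- sos_program(vnames)
  gcol <- sp_add_free(prog, "gamma")
  lam_expos <- {
    M <- monomials_upto(nv, degt)
    M[rowSums(M[, seq_len(n), drop = FALSE]) == 0, , drop = FALSE]
  }
  lam_cols <- vapply(seq_len(nrow(lam_expos)), function(i)
    sp_add_free(prog, paste0("lam", i)), 0)
  basis_mu <- monomials_upto(nv, 1)
  for (j in seq_len(np)) sp_add_gram(prog, paste0("mu", j), basis_mu)
  caps <- list(total = max(2, ceiling((degt + 2) / 2)),
               groups = list(list(idx = seq_len(n), cap = 1),
                             list(idx = n + seq_len(np), cap = max(1, ceiling(degt / 2) + 1))))

  sphere <- poly_const(vnames, beta^2)
  for (v in vnames[seq_len(n)]) sphere <- poly_sub(sphere, poly_pow(poly_var(vnames, v), 2))
  boxp <- lapply(seq_len(np), function(j)
    poly_sub(poly_const(vnames, 1), poly_pow(poly_var(vnames, vnames[n + j]), 2)))

  sp_add_chunk(prog, matrix(0, 1, nv), 1, gcol)
  sp_add_poly(prog, Sc, NA_integer_, scale = -1)
  for (i in seq_len(nrow(lam_expos))) {
    lp <- poly_mul(poly_monomial(vnames, lam_expos[i, ]), sphere)
    sp_add_poly(prog, lp, lam_cols[i], scale = -1)
  }
  for (j in seq_len(np)) sp_add_gram_poly(prog, paste0("mu", j), factor = boxp[[j]], sign = -1)
  sp_add_pruned_gram(prog, "Q0", .capped_monomials(nv, caps))
  sp_add_gram_poly(prog, "Q0", sign = -1)
  sp_objective(prog, gcol, 1)
  sol <- sp_solve(prog, tol = tol)
  .accept_solution(sol, "structural extraction")
  gamma <- sol$free[["gamma"]]

  ext <- .extract_moments(sol, nv, seq_len(n), t_idx = n + seq_len(np),
                          rank_tol = rank_tol)
  eval_S <- function(v, tt) poly_eval(Sc, stats::setNames(c(v, tt), vnames))
  starts <- sphere_grid(n, 12)
  best_fb <- -Inf; v_fb <- starts[1, ]; t_fb <- rep(0, np)
  corners <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), np)))
  for (i in seq_len(nrow(starts))) for (r in seq_len(nrow(corners))) {
    opt <- stats::optim(c(starts[i, ], corners[r, ]), function(w) {
      v <- w[seq_len(n)]; tt <- pmin(pmax(w[n + seq_len(np)], -1), 1)
      nw <- sqrt(sum(v^2)); if (nw < 1e-9) return(0)
      -eval_S(beta * v / nw, tt)
    }, method = "Nelder-Mead", control = list(reltol = 1e-10, maxit = 800))
    if (-opt$value > best_fb) {
      best_fb <- -opt$value
      v_fb <- opt$par[seq_len(n)] / sqrt(sum(opt$par[seq_len(n)]^2))
      t_fb <- pmin(pmax(opt$par[n + seq_len(np)], -1), 1)
    }
  }
  kk <- which(abs(v_fb) > 1e-9)[1]
  if (!is.na(kk) && v_fb[kk] < 0) v_fb <- -v_fb

  dual_ok <- isTRUE(ext$ok) && ext$rank_ratio < rank_tol && !anyNA(ext$t) &&
    abs(eval_S(beta * ext$direction, pmin(pmax(ext$t, -1), 1)) - gamma) <=
      agree_tol * max(abs(gamma), 1e-9)
  fb_ok <- abs(best_fb - gamma) <= agree_tol * max(abs(gamma), 1e-9)
  if (dual_ok) {
    tt <- pmin(pmax(ext$t, -1), 1)
    list(param_point = stats::setNames(mid + wid * tt, pn),
         direction = ext$direction, xhat = beta * ext$direction,
         energy_bound = gamma, route = "dual_moment",
         rank_ratio = ext$rank_ratio, dual_value = gamma, fallback_value = best_fb)
  } else if (fb_ok) {
    list(param_point = stats::setNames(mid + wid * t_fb, pn),
         direction = v_fb, xhat = beta * v_fb,
         energy_bound = best_fb, route = "fallback_search",
         rank_ratio = if (is.null(ext$rank_ratio)) NA_real_ else ext$rank_ratio,
         dual_value = gamma, fallback_value = best_fb)
  } else {
    stop(errorCondition(sprintf(
      "structural extraction failed: dual level %.6g vs fallback %.6g disagree by more than %.0f%%",
      gamma, best_fb, 100 * agree_tol),
      class = c("discrim_extraction_error", "error")))
  }
}
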