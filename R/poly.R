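# Sparse multivariate polynomial arithmetic.
#
# A "polyform" stores a polynomial over a fixed, ordered variable set as an
# exponent matrix (terms x variables) plus a coefficient vector, kept in a
# canonical order (total degree, then lexicographic).  This is the workhorse
# for symbolic Jacobians, steady-state shifts and the SOS assembly; it is
# deliberately minimal — no rational-function simplification, no Groebner
# machinery.

new_polyform <- function(vars, expo, coef) {
  expo <- matrix(as.numeric(expo), ncol = length(vars))
  structure(list(vars = vars, expo = expo, coef = as.numeric(coef)),
            class = "polyform")
}

#' @export
print.polyform <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.polyform <- function(x, digits = 6, ...) {
  if (length(x$coef) == 0) return("0")
  terms <- vapply(seq_along(x$coef), function(i) {
    e <- x$expo[i, ]
    mono <- paste0(x$vars[e > 0],
                   ifelse(e[e > 0] > 1, paste0("^", e[e > 0]), ""),
                   collapse = "*")
    cf <- signif(x$coef[i], digits)
    if (mono == "") as.character(cf)
    else if (cf == 1) mono
    else if (cf == -1) paste0("-", mono)
    else paste0(cf, "*", mono)
  }, "")
  paste(terms, collapse = " + ")
}

poly_zero <- function(vars) {
  new_polyform(vars, matrix(0, 0, length(vars)), numeric(0))
}

poly_const <- function(vars, c) {
  if (c == 0) return(poly_zero(vars))
  new_polyform(vars, matrix(0, 1, length(vars)), c)
}

poly_var <- function(vars, name) {
  stopifnot(name %in% vars)
  e <- matrix(0, 1, length(vars))
  e[1, match(name, vars)] <- 1
  new_polyform(vars, e, 1)
}

# monomial from an exponent vector
poly_monomial <- function(vars, expo, coef = 1) {
  new_polyform(vars, matrix(expo, 1), coef)
}

is_polyform <- function(p) inherits(p, "polyform")

# collapse duplicate monomials, drop zeros, sort canonically
poly_canon <- function(p, drop_tol = 0) {
  if (length(p$coef) == 0) return(p)
  key <- apply(p$expo, 1, paste, collapse = ",")
  coef <- as.numeric(tapply(p$coef, key, sum))
  keys <- names(tapply(p$coef, key, sum))
  expo <- do.call(rbind, lapply(strsplit(keys, ","), as.numeric))
  keep <- abs(coef) > drop_tol
  coef <- coef[keep]; expo <- expo[keep, , drop = FALSE]
  if (length(coef) == 0) return(poly_zero(p$vars))
  deg <- rowSums(expo)
  ord <- do.call(order, c(list(deg), lapply(seq_len(ncol(expo)), function(j) -expo[, j])))
  new_polyform(p$vars, expo[ord, , drop = FALSE], coef[ord])
}

poly_add <- function(a, b) {
  stopifnot(identical(a$vars, b$vars))
  poly_canon(new_polyform(a$vars, rbind(a$expo, b$expo), c(a$coef, b$coef)))
}

poly_neg <- function(a) { a$coef <- -a$coef; a }

poly_sub <- function(a, b) poly_add(a, poly_neg(b))

poly_scale <- function(a, s) { a$coef <- a$coef * s; poly_canon(a) }

poly_mul <- function(a, b) {
  stopifnot(identical(a$vars, b$vars))
  na <- length(a$coef); nb <- length(b$coef)
  if (na == 0 || nb == 0) return(poly_zero(a$vars))
  ia <- rep(seq_len(na), each = nb); ib <- rep(seq_len(nb), times = na)
  poly_canon(new_polyform(a$vars,
                          a$expo[ia, , drop = FALSE] + b$expo[ib, , drop = FALSE],
                          a$coef[ia] * b$coef[ib]))
}

poly_pow <- function(a, k) {
  stopifnot(k >= 0, k == round(k))
  out <- poly_const(a$vars, 1)
  while (k > 0) { out <- poly_mul(out, a); k <- k - 1 }
  out
}

poly_degree <- function(p) if (length(p$coef) == 0) 0 else max(rowSums(p$expo))

# degree restricted to a subset of variables
poly_degree_in <- function(p, vars) {
  if (length(p$coef) == 0) return(0)
  j <- match(vars, p$vars)
  max(rowSums(p$expo[, j, drop = FALSE]))
}

is_poly_constant <- function(p) {
  length(p$coef) == 0 || all(rowSums(p$expo) == 0)
}

poly_constant_value <- function(p) {
  if (length(p$coef) == 0) 0 else sum(p$coef[rowSums(p$expo) == 0])
}

# evaluate at a named point (vector or list); vectorized over point rows if
# given a matrix with columns named after the variables
poly_eval <- function(p, point) {
  if (is.matrix(point)) {
    x <- point[, p$vars, drop = FALSE]
    out <- numeric(nrow(x))
    for (i in seq_along(p$coef)) {
      e <- p$expo[i, ]
      term <- rep(p$coef[i], nrow(x))
      for (j in which(e > 0)) term <- term * x[, j]^e[j]
      out <- out + term
    }
    return(out)
  }
  x <- as.numeric(point[p$vars])
  if (anyNA(x)) stop("missing value for variable(s): ",
                     paste(p$vars[is.na(x)], collapse = ", "))
  s <- 0
  for (i in seq_along(p$coef)) s <- s + p$coef[i] * prod(x^p$expo[i, ])
  s
}

poly_diff <- function(p, var) {
  j <- match(var, p$vars)
  stopifnot(!is.na(j))
  keep <- p$expo[, j] > 0
  if (!any(keep)) return(poly_zero(p$vars))
  expo <- p$expo[keep, , drop = FALSE]
  coef <- p$coef[keep] * expo[, j]
  expo[, j] <- expo[, j] - 1
  poly_canon(new_polyform(p$vars, expo, coef))
}

# substitute var_i -> scale_i * var_i + shift_i (affine change of coordinates)
poly_subst_affine <- function(p, shift = NULL, scale = NULL) {
  k <- length(p$vars)
  if (is.null(shift)) shift <- stats::setNames(rep(0, k), p$vars)
  if (is.null(scale)) scale <- stats::setNames(rep(1, k), p$vars)
  sh <- rep(0, k); sc <- rep(1, k)
  sh[match(names(shift), p$vars)] <- as.numeric(shift)
  sc[match(names(scale), p$vars)] <- as.numeric(scale)
  subs <- lapply(seq_len(k), function(j) {
    poly_add(poly_scale(poly_var(p$vars, p$vars[j]), sc[j]),
             poly_const(p$vars, sh[j]))
  })
  poly_compose(p, subs)
}

# substitute each variable by a polyform over the same variable set
poly_compose <- function(p, subs) {
  out <- poly_zero(p$vars)
  for (i in seq_along(p$coef)) {
    term <- poly_const(p$vars, p$coef[i])
    for (j in which(p$expo[i, ] > 0))
      term <- poly_mul(term, poly_pow(subs[[j]], p$expo[i, j]))
    out <- poly_add(out, term)
  }
  out
}

# re-express over a larger variable set (variables must be a superset)
poly_extend_vars <- function(p, vars) {
  stopifnot(all(p$vars %in% vars))
  expo <- matrix(0, nrow(p$expo), length(vars))
  expo[, match(p$vars, vars)] <- p$expo
  new_polyform(vars, expo, p$coef)
}

# drop variables that do not occur
poly_restrict_vars <- function(p, vars) {
  j <- match(vars, p$vars)
  if (any(is.na(j))) stop("not a subset of the polynomial's variables")
  other <- setdiff(seq_along(p$vars), j)
  if (length(p$coef) && any(p$expo[, other] > 0))
    stop("polynomial involves dropped variables")
  new_polyform(vars, p$expo[, j, drop = FALSE], p$coef)
}

# --- parsing R expressions into polyforms -----------------------------------

#' Parse an expression string into a polynomial
#'
#' Accepts the plain infix grammar `+ - * / ^ ( )` over declared variables,
#' named constants, and numeric literals.  Division is only admitted when the
#' divisor is a numeric constant; anything else signals a classed
#' `discrim_rational_error`, which model constructors use to flag
#' rational-only (e.g. Michaelis-Menten) right-hand sides.
#'
#' @param text expression string, or a language object
#' @param vars character vector of symbolic variable names
#' @param consts named numeric vector of constants substituted at parse time
#' @return a `polyform`
#' @keywords internal
poly_parse <- function(text, vars, consts = numeric(0)) {
  lang <- if (is.character(text)) str2lang(text) else text
  rec <- function(e) {
    if (is.numeric(e)) return(poly_const(vars, as.numeric(e)))
    if (is.symbol(e)) {
      nm <- as.character(e)
      if (nm %in% vars) return(poly_var(vars, nm))
      if (nm %in% names(consts)) return(poly_const(vars, consts[[nm]]))
      stop(errorCondition(paste0("undeclared symbol '", nm, "' in expression '",
                                 deparse1(lang), "'"),
                          class = c("discrim_symbol_error", "discrim_validation_error")))
    }
    if (!is.call(e)) stop("cannot parse expression component: ", deparse1(e))
    op <- as.character(e[[1]])
    if (op == "(") return(rec(e[[2]]))
    if (op == "+" && length(e) == 2) return(rec(e[[2]]))
    if (op == "-" && length(e) == 2) return(poly_neg(rec(e[[2]])))
    if (op == "+") return(poly_add(rec(e[[2]]), rec(e[[3]])))
    if (op == "-") return(poly_sub(rec(e[[2]]), rec(e[[3]])))
    if (op == "*") return(poly_mul(rec(e[[2]]), rec(e[[3]])))
    if (op == "^") {
      k <- e[[3]]
      if (!is.numeric(k) || k < 0 || k != round(k))
        stop(errorCondition("exponent must be a nonnegative integer",
                            class = "discrim_validation_error"))
      return(poly_pow(rec(e[[2]]), k))
    }
    if (op == "/") {
      den <- rec(e[[3]])
      if (!is_poly_constant(den))
        stop(errorCondition(paste0("non-polynomial (rational) term in '",
                                   deparse1(lang), "'"),
                            class = "discrim_rational_error"))
      d <- poly_constant_value(den)
      if (d == 0) stop(errorCondition("division by zero constant",
                                      class = "discrim_validation_error"))
      return(poly_scale(rec(e[[2]]), 1 / d))
    }
    stop(errorCondition(paste0("unsupported operator '", op, "'"),
                        class = "discrim_validation_error"))
  }
  poly_canon(rec(lang))
}

# all monomial exponent vectors in `nv` variables with total degree in
# [dmin, dmax], in canonical order; returns a matrix (one row per monomial)
monomials_upto <- function(nv, dmax, dmin = 0) {
  grow <- function(prefix, left, slots) {
    if (slots == 1) return(matrix(c(prefix, left), 1))
    do.call(rbind, lapply(0:left, function(k) grow(c(prefix, k), left - k, slots - 1)))
  }
  out <- do.call(rbind, lapply(dmin:dmax, function(d) {
    if (nv == 0) return(if (d == 0) matrix(0, 1, 0) else NULL)
    grow(numeric(0), d, nv)
  }))
  out[, rev(seq_len(ncol(out))), drop = FALSE]
}

# named coefficient lookup: coefficient of a given exponent vector
poly_coef_of <- function(p, expo) {
  if (length(p$coef) == 0) return(0)
  hit <- which(colSums(t(p$expo) != expo) == 0)
  if (length(hit) == 0) 0 else sum(p$coef[hit])
}

# maximum |difference| between two polynomials' coefficients
poly_coef_dist <- function(a, b) {
  d <- poly_sub(a, b)
  if (length(d$coef) == 0) 0 else max(abs(d$coef))
}
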