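# Sum-of-squares programme assembly.
#
# An SOS programme here is a semidefinite programme in the standard primal
# form consumed by sdp_solve(): decision variables are free scalars
# (polynomial coefficients, gain levels) followed by Gram matrices, and each
# polynomial identity contributes one equality row per monomial.  Gram
# matrices are stored in svec form (off-diagonals times sqrt(2)), so the
# polynomial represented by a Gram block with monomial basis z is
#    sum_i Q_ii z_i^2 + sqrt(2) * sum_{i<j} q_ij z_i z_j ,  q_ij = sqrt(2) Q_ij.

sos_program <- function(vars) {
  e <- new.env(parent = emptyenv())
  e$vars <- vars
  e$nvar <- 0L
  e$free <- integer(0)          # named: free variable name -> column
  e$grams <- list()             # name -> list(cols, basis, k)
  e$rows <- new.env(hash = TRUE, parent = emptyenv())
  e$nrow <- 0L
  e$expo_chunks <- list()       # per-row exponent vectors, in chunks
  e$ti <- list(); e$tj <- list(); e$tv <- list()   # triplet chunks
  e$b <- numeric(0)
  e$obj <- list(i = integer(0), v = numeric(0))
  e$grams_started <- FALSE
  class(e) <- "sos_program"
  e
}

sp_add_free <- function(prog, name) {
  if (prog$grams_started)
    stop("internal: free variables must be declared before Gram blocks")
  prog$nvar <- prog$nvar + 1L
  prog$free[name] <- prog$nvar
  prog$nvar
}

sp_add_gram <- function(prog, name, basis_expo) {
  prog$grams_started <- TRUE
  k <- nrow(basis_expo)
  cols <- prog$nvar + seq_len(svec_dim(k))
  prog$nvar <- prog$nvar + svec_dim(k)
  prog$grams[[name]] <- list(cols = cols, basis = basis_expo, k = k)
  invisible(name)
}

# map exponent rows to equality-row indices, creating rows as needed
sp_rows_of <- function(prog, expo) {
  keys <- apply(expo, 1, paste, collapse = ",")
  idx <- integer(length(keys))
  for (i in seq_along(keys)) {
    r <- prog$rows[[keys[i]]]
    if (is.null(r)) {
      prog$nrow <- prog$nrow + 1L
      r <- prog$nrow
      prog$rows[[keys[i]]] <- r
      prog$expo_chunks[[length(prog$expo_chunks) + 1L]] <- expo[i, ]
      prog$b[r] <- 0
    }
    idx[i] <- r
  }
  idx
}

# add  sum_t coef_t * monomial_t * x_col  to the constraint rows
# (col = NA adds a constant contribution, i.e. moves to the right-hand side)
sp_add_chunk <- function(prog, expo, coef, col) {
  keep <- coef != 0
  if (!any(keep)) return(invisible())
  expo <- expo[keep, , drop = FALSE]; coef <- coef[keep]
  col <- if (length(col) == 1) rep(col, length(coef)) else col[keep]
  rows <- sp_rows_of(prog, expo)
  isconst <- is.na(col)
  if (any(isconst)) {
    for (i in which(isconst)) prog$b[rows[i]] <- prog$b[rows[i]] - coef[i]
  }
  if (any(!isconst)) {
    n <- length(prog$ti) + 1L
    prog$ti[[n]] <- rows[!isconst]
    prog$tj[[n]] <- col[!isconst]
    prog$tv[[n]] <- coef[!isconst]
  }
  invisible()
}

sp_add_poly <- function(prog, poly, col = NA_integer_, scale = 1) {
  if (length(poly$coef) == 0) return(invisible())
  stopifnot(identical(poly$vars, prog$vars))
  sp_add_chunk(prog, poly$expo, poly$coef * scale, col)
}

# add the polynomial of a whole Gram block, each svec coordinate times an
# optional fixed polynomial factor: sign * factor * (z' Q z)
sp_add_gram_poly <- function(prog, name, factor = NULL, sign = 1) {
  g <- prog$grams[[name]]
  k <- g$k; basis <- g$basis
  ii <- jj <- integer(svec_dim(k)); pos <- 0L
  for (j in seq_len(k)) for (i in seq_len(j)) { pos <- pos + 1L; ii[pos] <- i; jj[pos] <- j }
  expo <- basis[ii, , drop = FALSE] + basis[jj, , drop = FALSE]
  scale <- ifelse(ii == jj, 1, sqrt(2)) * sign
  if (is.null(factor)) {
    sp_add_chunk(prog, expo, scale, g$cols)
  } else {
    stopifnot(identical(factor$vars, prog$vars))
    for (t in seq_along(factor$coef)) {
      sp_add_chunk(prog, sweep(expo, 2, factor$expo[t, ], "+"),
                   scale * factor$coef[t], g$cols)
    }
  }
  invisible()
}

# add  sign * sum_k d(z' Q z)/d v_k * f[[k]]  (a Lie derivative along f),
# where f is a named list of polyforms keyed by differentiation variable
sp_add_gram_lie <- function(prog, name, f, sign = 1) {
  g <- prog$grams[[name]]
  k <- g$k; basis <- g$basis
  pos <- 0L
  for (j in seq_len(k)) for (i in seq_len(j)) {
    pos <- pos + 1L
    zz <- new_polyform(prog$vars, matrix(basis[i, ] + basis[j, ], 1),
                       if (i == j) 1 else sqrt(2))
    acc <- poly_zero(prog$vars)
    for (vn in names(f)) {
      dz <- poly_diff(zz, vn)
      if (length(dz$coef)) acc <- poly_add(acc, poly_mul(dz, f[[vn]]))
    }
    if (length(acc$coef))
      sp_add_chunk(prog, acc$expo, sign * acc$coef, g$cols[pos])
  }
  invisible()
}

# Diagonal-consistency pruning of a Gram basis: drop any basis monomial m
# whose square 2m is outside the constraint support and cannot be formed as a
# product of two other (surviving) basis monomials — its Gram diagonal would
# be forced to zero, which kills strict feasibility and stalls the solver.
# Iterated to a fixed point.
prune_gram_basis <- function(basis, support) {
  skey <- unique(apply(support, 1, paste, collapse = ","))
  repeat {
    nb <- nrow(basis)
    if (nb == 0) break
    keys2 <- apply(2 * basis, 1, paste, collapse = ",")
    keep <- logical(nb)
    prodkeys <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_len(nb)) for (j in seq_len(nb)) {
      if (i == j) next
      k <- paste(basis[i, ] + basis[j, ], collapse = ",")
      prodkeys[[k]] <- TRUE
    }
    for (i in seq_len(nb))
      keep[i] <- keys2[i] %in% skey || !is.null(prodkeys[[keys2[i]]])
    if (all(keep)) break
    basis <- basis[keep, , drop = FALSE]
  }
  basis
}

# constraint-support exponent matrix accumulated so far
sp_current_support <- function(prog) {
  if (length(prog$expo_chunks) == 0) return(matrix(0, 0, length(prog$vars)))
  do.call(rbind, prog$expo_chunks)
}

# add a Gram block with its candidate basis pruned against the support of
# the contributions assembled so far (call it after all other contributions)
sp_add_pruned_gram <- function(prog, name, candidate_basis) {
  basis <- prune_gram_basis(candidate_basis, sp_current_support(prog))
  sp_add_gram(prog, name, basis)
  basis
}

sp_objective <- function(prog, cols, vals) {
  prog$obj$i <- c(prog$obj$i, cols)
  prog$obj$v <- c(prog$obj$v, vals)
  invisible()
}

# objective entries selecting the trace of the Gram diagonal over basis
# monomials of total degree one (the quadratic part of the polynomial)
sp_objective_trace_quadratic <- function(prog, name, weight = 1) {
  g <- prog$grams[[name]]
  deg1 <- which(rowSums(g$basis) == 1)
  pos <- 0L; cols <- integer(0)
  for (j in seq_len(g$k)) for (i in seq_len(j)) {
    pos <- pos + 1L
    if (i == j && i %in% deg1) cols <- c(cols, g$cols[pos])
  }
  sp_objective(prog, cols, rep(weight, length(cols)))
}

# full Gram trace of a block (used for parametric storage, where every basis
# element contributes quadratic mass somewhere in the box)
sp_objective_gram_trace <- function(prog, name, weight = 1) {
  g <- prog$grams[[name]]
  pos <- 0L; cols <- integer(0)
  for (j in seq_len(g$k)) for (i in seq_len(j)) {
    pos <- pos + 1L
    if (i == j) cols <- c(cols, g$cols[pos])
  }
  sp_objective(prog, cols, rep(weight, length(cols)))
}

sp_solve <- function(prog, tol = 1e-6, max_iter = 40000L, verbose = FALSE) {
  i <- unlist(prog$ti); j <- unlist(prog$tj); v <- unlist(prog$tv)
  A <- Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(prog$nrow, prog$nvar))
  b <- prog$b
  cvec <- numeric(prog$nvar)
  cvec[prog$obj$i] <- cvec[prog$obj$i] + prog$obj$v
  cone <- list(free = length(prog$free), nonneg = 0L,
               psd = vapply(prog$grams, `[[`, 0L, "k"))
  res <- sdp_solve(A, b, cvec, cone, tol = tol, max_iter = max_iter, verbose = verbose)
  grams <- lapply(prog$grams, function(g) unsvec(res$x[g$cols], g$k))
  expo <- do.call(rbind, prog$expo_chunks)
  list(status = res$status, objective = res$objective,
       free = stats::setNames(res$x[prog$free], names(prog$free)),
       grams = grams, sdp = res,
       moments = list(expo = expo, y = res$y))
}

# polynomial represented by a solved Gram block (in programme variables)
gram_polynomial <- function(prog, name, Q) {
  g <- prog$grams[[name]]
  out <- poly_zero(prog$vars)
  for (j in seq_len(g$k)) for (i in seq_len(j)) {
    cf <- if (i == j) Q[i, i] else 2 * Q[i, j]
    if (cf != 0)
      out <- poly_add(out, new_polyform(prog$vars,
                                        matrix(g$basis[i, ] + g$basis[j, ], 1), cf))
  }
  poly_canon(out, drop_tol = 0)
}

# dual-moment lookup: value of the moment for a given exponent vector
moment_of <- function(sol, expo) {
  hit <- which(colSums(t(sol$moments$expo) != expo) == 0)
  if (length(hit) == 0) return(NA_real_)
  sol$moments$y[hit[1]]
}

# moment matrix over a monomial basis (exponent matrix rows)
moment_matrix <- function(sol, basis) {
  k <- nrow(basis)
  M <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in i:k)
    M[i, j] <- M[j, i] <- moment_of(sol, basis[i, ] + basis[j, ])
  M
}

# --- certificate re-verification -------------------------------------------

# Independently re-check a solved SOS identity: the residual polynomial
# (target minus what the Gram blocks and free coefficients represent) is
# absorbed into the main Gram block so the identity holds to rounding, and
# the PSD-ness of every corrected Gram is then checked by eigendecomposition.
sos_verify <- function(prog, sol, target_residual, main = "Q0",
                       eig_tol = 1e-5) {
  Q <- sol$grams[[main]]
  g <- prog$grams[[main]]
  resid <- target_residual
  unabsorbed <- 0
  if (length(resid$coef)) {
    for (t in seq_along(resid$coef)) {
      mu <- resid$expo[t, ]
      # absorb into a diagonal Gram entry when 2*basis_i == mu ...
      half <- mu / 2
      di <- which(colSums(t(g$basis) != half) == 0)
      if (length(di)) {
        Q[di[1], di[1]] <- Q[di[1], di[1]] + resid$coef[t]
      } else {
        # ... otherwise into the first off-diagonal pair with that product
        done <- FALSE
        for (i in seq_len(g$k)) {
          if (done) break
          for (j in seq_len(g$k)) {
            if (i < j && all(g$basis[i, ] + g$basis[j, ] == mu)) {
              Q[i, j] <- Q[i, j] + resid$coef[t] / 2
              Q[j, i] <- Q[j, i] + resid$coef[t] / 2
              done <- TRUE; break
            }
          }
        }
        if (!done) unabsorbed <- max(unabsorbed, abs(resid$coef[t]))
      }
    }
  }
  eigs <- lapply(sol$grams, function(M) eigen((M + t(M)) / 2, symmetric = TRUE,
                                              only.values = TRUE)$values)
  eigs[[main]] <- eigen((Q + t(Q)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min_eig <- vapply(eigs, min, 0)
  scale <- vapply(sol$grams, function(M) max(abs(M), 1), 0)
  ok <- all(min_eig >= -eig_tol * scale) && unabsorbed <= eig_tol
  list(ok = ok, min_eig = min_eig, unabsorbed = unabsorbed,
       residual = if (length(resid$coef)) max(abs(resid$coef)) else 0,
       corrected_main = Q)
}

# --- plain SOS membership test ---------------------------------------------

#' Test whether a polynomial is a sum of squares
#'
#' Builds the Gram-matrix semidefinite feasibility problem for the given
#' polynomial and solves it.  A feasible solution is returned as a certified
#' Gram factorization; infeasibility means the polynomial is not SOS (it may
#' still be nonnegative — the Motzkin polynomial is the classical example).
#'
#' @param p a `polyform`, or an expression string
#' @param vars variable names (required when `p` is a string)
#' @param tol solver tolerance
#' @return list with `is_sos`, the Gram matrix `Q`, the monomial `basis`,
#'   the identity `residual` and the solver `status`
#' @export
sos_check <- function(p, vars = NULL, tol = 1e-7) {
  if (is.character(p)) p <- poly_parse(p, vars)
  vars <- p$vars
  if (length(p$coef) == 0)
    return(list(is_sos = TRUE, Q = matrix(0, 0, 0), basis = NULL, residual = 0,
                status = "optimal"))
  dmax <- poly_degree(p)
  if (dmax %% 2 == 1) return(list(is_sos = FALSE, status = "odd degree"))
  dmin <- min(rowSums(p$expo))
  prog <- sos_program(vars)
  sp_add_poly(prog, p, col = NA_integer_, scale = -1)  # z'Qz = p
  basis <- sp_add_pruned_gram(prog, "Q0",
                              monomials_upto(length(vars), dmax / 2,
                                             dmin = floor(dmin / 2)))
  if (nrow(basis) == 0) return(list(is_sos = FALSE, status = "empty basis"))
  sp_add_gram_poly(prog, "Q0", sign = 1)
  sol <- sp_solve(prog, tol = tol)
  if (sol$status != "optimal")
    return(list(is_sos = FALSE, status = sol$status))
  Q <- sol$grams$Q0
  rec <- gram_polynomial(prog, "Q0", Q)
  resid <- poly_coef_dist(rec, p)
  ver <- sos_verify(prog, sol, poly_sub(p, rec))
  list(is_sos = ver$ok, Q = ver$corrected_main, basis = basis,
       residual = resid, min_eig = min(ver$min_eig), status = sol$status)
}
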