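# First-order conic solver for semidefinite programmes.
#
# Solves   min c'x   s.t.  A x = b,  x in K,
# where K is a Cartesian product  R^free x R+^nonneg x PSD(s1) x PSD(s2) x ...
# (PSD blocks in scaled-vectorized "svec" form, off-diagonals times sqrt(2)).
#
# The algorithm is operator splitting (ADMM) on the homogeneous self-dual
# embedding, so it returns either a primal/dual solution pair or a
# certificate of primal infeasibility / unboundedness.  The only per-iteration
# work is one cached linear solve and a eigendecomposition per PSD block,
# which keeps the SOS programmes of this package (a few thousand constraints,
# Gram blocks up to a few hundred) comfortably within desktop budgets.

svec <- function(M) {
  k <- nrow(M)
  idx <- upper.tri(M, diag = TRUE)
  v <- M[idx]
  mult <- matrix(sqrt(2), k, k); diag(mult) <- 1
  v * mult[idx]
}

unsvec <- function(v, k) {
  M <- matrix(0, k, k)
  idx <- upper.tri(M, diag = TRUE)
  mult <- matrix(1 / sqrt(2), k, k); diag(mult) <- 1
  M[idx] <- v * mult[idx]
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

svec_dim <- function(k) k * (k + 1) / 2

# linear index of entry (i,j), i<=j, within svec of a k x k matrix
svec_index <- function(i, j, k) {
  stopifnot(i <= j)
  j * (j - 1) / 2 + i
}

cone_dim <- function(cone) {
  cone$free + cone$nonneg + sum(vapply(cone$psd, svec_dim, 0))
}

# projection onto K (dual = TRUE projects onto the dual cone K*)
cone_project <- function(x, cone, dual = FALSE) {
  out <- x
  pos <- 0
  if (cone$free > 0) {
    idx <- pos + seq_len(cone$free)
    if (dual) out[idx] <- 0          # dual of free is {0}
    pos <- pos + cone$free
  }
  if (cone$nonneg > 0) {
    idx <- pos + seq_len(cone$nonneg)
    out[idx] <- pmax(out[idx], 0)
    pos <- pos + cone$nonneg
  }
  for (k in cone$psd) {
    idx <- pos + seq_len(svec_dim(k))
    M <- unsvec(x[idx], k)
    e <- eigen(M, symmetric = TRUE)
    pos_ev <- pmax(e$values, 0)
    out[idx] <- svec(e$vectors %*% (pos_ev * t(e$vectors)))
    pos <- pos + svec_dim(k)
  }
  out
}

# Ruiz equilibration with cone-uniform column scaling on PSD blocks
.sdp_equilibrate <- function(A, cone, iters = 10) {
  m <- nrow(A); n <- ncol(A)
  D <- rep(1, m); E <- rep(1, n)
  blocks <- list()
  pos <- cone$free + cone$nonneg
  for (k in cone$psd) {
    blocks[[length(blocks) + 1]] <- pos + seq_len(svec_dim(k))
    pos <- pos + svec_dim(k)
  }
  group_max <- function(vals, idx, len) {
    out <- rep(1, len)
    if (length(vals)) {
      agg <- tapply(vals, idx, max)
      out[as.integer(names(agg))] <- pmax(as.numeric(agg), 1e-12)
    }
    out
  }
  for (it in seq_len(iters)) {
    tr <- Matrix::mat2triplet(A)
    ax <- abs(tr$x)
    d <- 1 / sqrt(group_max(ax, tr$i, m))
    e <- 1 / sqrt(group_max(ax * d[tr$i], tr$j, n))
    for (idx in blocks) e[idx] <- exp(mean(log(e[idx])))
    A <- Matrix::Diagonal(x = d) %*% A %*% Matrix::Diagonal(x = e)
    D <- D * d
    E <- E * e
  }
  list(A = methods::as(A, "CsparseMatrix"), D = D, E = E)
}

#' Solve a conic (semidefinite) programme
#'
#' @param A constraint matrix (dense or `Matrix` sparse), `m x n`
#' @param b right-hand side of the equality constraints
#' @param c objective vector (length `n`); all-zero for feasibility problems
#' @param cone list with elements `free`, `nonneg` (counts) and `psd`
#'   (integer vector of PSD block orders); blocks appear in `x` in that order
#' @param tol relative stopping tolerance on primal/dual residuals and gap
#' @param max_iter iteration cap
#' @param alpha over-relaxation parameter in (1, 2)
#' @param scale apply Ruiz equilibration before solving
#' @param verbose print residuals every few hundred iterations
#' @return list with `x`, `y` (equality duals), `z` (dual cone variable),
#'   `status` (`"optimal"`, `"infeasible"`, `"unbounded"` or `"max_iter"`),
#'   objective value and residuals
#' @export
sdp_solve <- function(A, b, c = rep(0, ncol(A)), cone = list(free = ncol(A), nonneg = 0, psd = integer(0)),
                      tol = 1e-6, max_iter = 20000L, alpha = 1.5,
                      scale = TRUE, verbose = FALSE, check_every = 25L) {
  cone$free <- if (is.null(cone$free)) 0L else cone$free
  cone$nonneg <- if (is.null(cone$nonneg)) 0L else cone$nonneg
  cone$psd <- if (is.null(cone$psd)) integer(0) else cone$psd
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  m <- nrow(A); n <- ncol(A)
  stopifnot(cone_dim(cone) == n, length(b) == m, length(c) == n)

  bn0 <- sqrt(sum(b^2)); cn0 <- sqrt(sum(c^2))
  if (scale) {
    eq <- .sdp_equilibrate(A, cone)
    As <- eq$A; D <- eq$D; E <- eq$E
  } else {
    As <- A; D <- rep(1, m); E <- rep(1, n)
  }
  bs <- D * b; cs <- E * c
  sigma <- 1 / max(sqrt(sum(bs^2)), 1e-6)
  rho <- 1 / max(sqrt(sum(cs^2)), 1e-6)
  bs <- sigma * bs; cs <- rho * cs

  # cached factorization of (I_m + A A') for the (I + Q) subproblem
  S <- as.matrix(Matrix::tcrossprod(As))
  diag(S) <- diag(S) + 1
  R <- chol(S)
  At <- Matrix::t(As)
  gram_solve <- function(w) {       # (I + A'A)^{-1} w  via Woodbury
    Aw <- as.numeric(As %*% w)
    w - as.numeric(At %*% backsolve(R, backsolve(R, Aw, transpose = TRUE)))
  }
  M_solve <- function(a, e) {       # [[I, -A'],[A, I]] (r;s) = (a;e)
    r <- gram_solve(a + as.numeric(At %*% e))
    s <- e - as.numeric(As %*% r)
    list(r = r, s = s)
  }
  d_vec_x <- cs; d_vec_y <- -bs
  g2 <- M_solve(d_vec_x, d_vec_y)
  denom <- 1 + sum(d_vec_x * g2$r) + sum(d_vec_y * g2$s)
  IQ_solve <- function(hx, hy, ht) {
    g1 <- M_solve(hx, hy)
    tau <- (ht + sum(d_vec_x * g1$r) + sum(d_vec_y * g1$s)) / denom
    list(x = g1$r - tau * g2$r, y = g1$s - tau * g2$s, tau = tau)
  }

  nx_idx <- seq_len(n); ny_idx <- n + seq_len(m); nt_idx <- n + m + 1L
  K <- n + m + 1L
  # one sweep of the splitting iteration on the stacked state z = (u, v)
  T_step <- function(z) {
    ux <- z[nx_idx]; uy <- z[ny_idx]; ut <- z[nt_idx]
    vx <- z[K + nx_idx]; vy <- z[K + ny_idx]; vt <- z[K + nt_idx]
    w <- IQ_solve(ux + vx, uy + vy, ut + vt)
    wx <- alpha * w$x + (1 - alpha) * ux
    wy <- alpha * w$y + (1 - alpha) * uy
    wt <- alpha * w$tau + (1 - alpha) * ut
    ux_new <- cone_project(wx - vx, cone, dual = FALSE)
    uy_new <- wy - vy
    ut_new <- max(wt - vt, 0)
    c(ux_new, uy_new, ut_new,
      vx - wx + ux_new, vy - wy + uy_new, vt - wt + ut_new)
  }

  z <- c(rep(0, n + m), 1, rep(0, n + m + 1))
  status <- "max_iter"; iters <- max_iter
  pres <- dres <- gap <- NA_real_

  # safeguarded Anderson acceleration (type II, restarted)
  aa_mem <- 10L
  Zh <- Gh <- NULL
  best_res <- Inf

  for (it in seq_len(max_iter)) {
    znew <- T_step(z)
    g <- znew - z
    resn <- sqrt(sum(g^2))
    if (resn > 5 * best_res || !is.finite(resn)) {
      Zh <- Gh <- NULL            # acceleration went astray: restart history
      best_res <- Inf
    } else {
      best_res <- min(best_res, resn)
      Zh <- cbind(Zh, z); Gh <- cbind(Gh, g)
      if (ncol(Zh) > aa_mem) { Zh <- Zh[, -1, drop = FALSE]; Gh <- Gh[, -1, drop = FALSE] }
    }
    if (!is.null(Gh) && ncol(Gh) >= 2) {
      dG <- Gh[, -1, drop = FALSE] - Gh[, -ncol(Gh), drop = FALSE]
      dZ <- Zh[, -1, drop = FALSE] - Zh[, -ncol(Zh), drop = FALSE]
      gam <- tryCatch(solve(crossprod(dG) + 1e-12 * sum(dG^2) * diag(ncol(dG)),
                            crossprod(dG, g)),
                      error = function(e) NULL)
      if (!is.null(gam) && all(is.finite(gam))) {
        z <- znew - (dZ + dG) %*% gam
        z <- as.numeric(z)
      } else z <- znew
    } else z <- znew

    # diagnostics and solution candidates always use the clean (projected)
    # iterate, not the Anderson-mixed one
    ux <- znew[nx_idx]; uy <- znew[ny_idx]; ut <- znew[nt_idx]
    vx <- znew[K + nx_idx]

    if (it %% check_every == 0 || it == max_iter) {
      if (ut > 1e-9) {
        xc <- E * ux / (sigma * ut)
        yc <- D * uy / (rho * ut)
        zc <- (vx / E) / (rho * ut)
        pr <- as.numeric(A %*% xc) - b
        dr <- c - as.numeric(Matrix::crossprod(A, yc)) - zc
        px <- sum(c * xc); dy <- sum(b * yc)
        pres <- sqrt(sum(pr^2)) / (1 + bn0)
        dres <- sqrt(sum(dr^2)) / (1 + cn0)
        gap <- abs(px - dy) / (1 + abs(px) + abs(dy))
        if (verbose && it %% (check_every * 20) == 0)
          message(sprintf("iter %6d  pres %.2e  dres %.2e  gap %.2e", it, pres, dres, gap))
        if (pres < tol && dres < tol && gap < tol) {
          status <- "optimal"; iters <- it
          break
        }
      }
      # infeasibility / unboundedness certificates; require the certificate
      # inner product to be significant relative to the iterate norm, so a
      # feasible problem with temporarily large duals is not misclassified
      ctx <- sum(cs * ux); bty <- sum(bs * uy)
      nuy <- sqrt(sum(uy^2)); nux <- sqrt(sum(ux^2))
      nb <- max(sqrt(sum(bs^2)), 1e-12); nc <- max(sqrt(sum(cs^2)), 1e-12)
      if (bty > 1e-7 * nb * nuy && nuy > 0) {
        w_inf <- -as.numeric(Matrix::crossprod(As, uy))
        res_inf <- sqrt(sum((w_inf - cone_project(w_inf, cone, dual = TRUE))^2))
        if (res_inf <= tol * bty) {
          status <- "infeasible"; iters <- it
          break
        }
      }
      if (ctx < -1e-7 * nc * nux && nux > 0) {
        res_unb <- sqrt(sum((as.numeric(As %*% ux))^2))
        if (res_unb <= tol * (-ctx)) {
          status <- "unbounded"; iters <- it
          break
        }
      }
    }
  }

  if (status %in% c("optimal", "max_iter") && ut > 1e-9) {
    x <- E * ux / (sigma * ut)
    y <- D * uy / (rho * ut)
    z <- (vx / E) / (rho * ut)
    obj <- sum(c * x)
  } else {
    x <- E * ux; y <- D * uy; z <- vx / E; obj <- NA_real_
  }
  list(x = x, y = y, z = z, status = status, iters = iters,
       pres = pres, dres = dres, gap = gap, objective = obj, tau = ut)
}
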