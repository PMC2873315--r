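# Linearized design machinery: Jacobian blocks of the concatenated system,
# the observability gramian, the optimal common initial direction (restricted
# gramian eigenproblem), and the frequency-response peak used for input
# design.

#' Linearize a difference system at the origin
#'
#' Returns the block matrices of the linearized concatenated system:
#' `A = diag(A1, A2)`, `B = (B1; B2)`, `C = (C1, -C2)`.
#'
#' @param diff_system a [concatenate_models()] result
#' @return object of class `lin_diff`
#' @export
linearize <- function(diff_system) {
  s1 <- diff_system$m1; s2 <- diff_system$m2
  A <- rbind(cbind(s1$A_lin, matrix(0, diff_system$n1, diff_system$n2)),
             cbind(matrix(0, diff_system$n2, diff_system$n1), s2$A_lin))
  B <- rbind(s1$B_lin, s2$B_lin)
  C <- cbind(s1$C_lin, -s2$C_lin)
  ev <- eigen(A, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop(errorCondition("linearized difference system is not Hurwitz; the design methods are inapplicable",
                        class = c("discrim_stability_error", "error")))
  structure(list(A = A, B = B, C = C,
                 A1 = s1$A_lin, A2 = s2$A_lin,
                 n1 = diff_system$n1, n2 = diff_system$n2,
                 q = diff_system$q, l = diff_system$l,
                 output_names = diff_system$output_names,
                 eigenvalues = ev),
            class = "lin_diff")
}

#' @export
print.lin_diff <- function(x, ...) {
  cat(sprintf("<lin_diff>  A: %dx%d (Hurwitz), B: %dx%d, C: %dx%d\n",
              nrow(x$A), ncol(x$A), nrow(x$B), ncol(x$B), nrow(x$C), ncol(x$C)))
  cat("  slowest mode Re(lambda) =", max(Re(x$eigenvalues)), "\n")
  invisible(x)
}

# resolve an output selector (names, indices, or NULL = all) to row indices
output_rows <- function(lin_or_ds, output = NULL) {
  nms <- lin_or_ds$output_names
  l <- length(nms)
  if (is.null(output)) return(seq_len(l))
  if (is.character(output)) {
    idx <- match(output, nms)
    if (anyNA(idx)) stop(validation_error(paste0("unknown output '", output[is.na(idx)][1], "'")))
    return(idx)
  }
  idx <- as.integer(output)
  if (any(idx < 1 | idx > l)) stop(validation_error("output index out of range"))
  idx
}

# solve A'P + PA + Q = 0 for Hurwitz A (vectorized Kronecker form)
lyapunov_solve <- function(A, Q) {
  n <- nrow(A)
  K <- kronecker(diag(n), t(A)) + kronecker(t(A), diag(n))
  P <- tryCatch(matrix(solve(K, -as.vector(Q)), n, n),
                error = function(e)
                  stop(errorCondition(paste0("Lyapunov solve failed: ", conditionMessage(e),
                                             " (condition estimate ", format(kappa(K)), ")"),
                                      class = c("discrim_solver_error", "error"))))
  (P + t(P)) / 2
}

#' Observability gramian and restricted matrix for initial-condition design
#'
#' Solves the observability Lyapunov equation `A'P + PA + C'C = 0`; the
#' output energy of the unforced linear system is `x(0)' P x(0)`.  For a
#' common perturbation `x1(0) = x2(0) = v` the energy is `v' R v` with
#' `R = P11 + P12 + P21 + P22`, so the optimal common direction is the top
#' eigenvector of `R`.
#'
#' @param lin a [linearize()] result
#' @param output optional output selector (names or indices); default all
#' @return object of class `gramian_design` with `P`, the blocks, `R`,
#'   the top eigenvalue `lambda_hat` and unit eigenvector `v_hat`
#' @export
observability_gramian <- function(lin, output = NULL) {
  rows <- output_rows(lin, output)
  C <- lin$C[rows, , drop = FALSE]
  P <- lyapunov_solve(lin$A, crossprod(C))
  resid <- t(lin$A) %*% P + P %*% lin$A + crossprod(C)
  if (norm(resid, "F") > 1e-8 * max(norm(crossprod(C), "F"), 1e-300))
    stop(errorCondition("Lyapunov residual exceeds tolerance", class = c("discrim_solver_error", "error")))
  n1 <- lin$n1; n2 <- lin$n2
  if (n1 != n2)
    stop(validation_error("common-initial-direction design requires n1 == n2"))
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  R <- P[i1, i1] + P[i1, i2] + P[i2, i1] + P[i2, i2]
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  structure(list(P = P, P11 = P[i1, i1], P12 = P[i1, i2],
                 P21 = P[i2, i1], P22 = P[i2, i2], R = R,
                 lambda_hat = e$values[1], eigen = e,
                 residual = norm(resid, "F"),
                 state_names = sub("_m1$", "", colnames(lin$A1) %||% paste0("x", i1))),
            class = "gramian_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Optimal common initial direction from the restricted gramian
#'
#' @param gd an [observability_gramian()] result
#' @param tie_tol relative gap below which the top eigenvalue is treated as
#'   multiple (a tie); the full eigenspace is then returned alongside a
#'   deterministic representative
#' @return list with `direction` (unit vector, first nonzero component
#'   positive), `energy_bound` (the top eigenvalue of `R`), `tie` flag and,
#'   on a tie, the orthonormal `basis` of the top eigenspace
#' @export
optimal_common_initial_direction <- function(gd, tie_tol = 1e-8) {
  vals <- gd$eigen$values
  if (max(abs(vals)) <= 1e-12)
    stop(errorCondition("restricted matrix R is numerically zero (identical models?): no discriminating direction exists",
                        class = c("discrim_degenerate_error", "error")))
  lam <- vals[1]
  mult <- which(vals >= lam * (1 - tie_tol))
  tie <- length(mult) > 1
  if (tie) {
    basis <- gd$eigen$vectors[, mult, drop = FALSE]
    # deterministic representative: lexicographically greatest first component
    first <- apply(basis, 2, function(v) v[which(abs(v) > 1e-12)[1]])
    v <- basis[, which.max(abs(first))]
  } else {
    basis <- NULL
    v <- gd$eigen$vectors[, 1]
  }
  v <- v / sqrt(sum(v^2))
  k <- which(abs(v) > 1e-12)[1]
  if (v[k] < 0) v <- -v
  list(direction = v, energy_bound = lam, tie = tie, basis = basis)
}

# largest singular value of G(jw) = C (jwI - A)^{-1} B
.freq_gain <- function(w, A, B, C) {
  G <- C %*% solve(diag(complex(imaginary = w), nrow(A)) - A, B)
  max(svd(G)$d)
}

#' Frequency-response peak of the linearized difference system
#'
#' Scans the largest singular value of `G(jw) = C(jwI - A)^{-1}B` over a
#' logarithmic frequency grid and refines the peak by golden-section search.
#' The peak gain is the induced L2 norm of the linear difference system, and
#' the peak ("critical") frequency is the recommended stimulation frequency.
#'
#' @param lin a [linearize()] result
#' @param output output selector: which rows of `C` are measured
#' @param grid_range frequency range (rad/time) of the log grid
#' @param grid_n number of grid points
#' @param flat_tol relative gain variation below which the response is
#'   declared flat (the grid minimum frequency is then returned, flagged)
#' @return object of class `freq_peak` with `omega0`, `gain`, the grid and
#'   the `flat` flag
#' @export
frequency_peak <- function(lin, output = NULL, grid_range = c(1e-3, 1e3),
                           grid_n = 2000, flat_tol = 1e-8) {
  if (lin$q < 1) stop(validation_error("frequency design requires at least one input"))
  rows <- output_rows(lin, output)
  C <- lin$C[rows, , drop = FALSE]
  ws <- exp(seq(log(grid_range[1]), log(grid_range[2]), length.out = grid_n))
  gains <- vapply(ws, .freq_gain, 0, A = lin$A, B = lin$B, C = C)
  i0 <- which.max(gains)
  flat <- (max(gains) - min(gains)) <= flat_tol * max(gains)
  if (flat) {
    return(structure(list(omega0 = ws[1], gain = gains[1], flat = TRUE,
                          grid = ws, grid_gain = gains, output = rows),
                     class = "freq_peak"))
  }
  lo <- ws[max(i0 - 1, 1)]; hi <- ws[min(i0 + 1, grid_n)]
  opt <- stats::optimize(function(w) -.freq_gain(w, lin$A, lin$B, C),
                         lower = lo, upper = hi, tol = lo * 1e-6)
  # golden-section may sit on a boundary if the grid bracketed poorly
  if (-opt$objective < gains[i0]) opt <- list(minimum = ws[i0], objective = -gains[i0])
  structure(list(omega0 = opt$minimum, gain = -opt$objective, flat = FALSE,
                 grid = ws, grid_gain = gains, output = rows),
            class = "freq_peak")
}

#' @export
print.freq_peak <- function(x, ...) {
  cat(sprintf("<freq_peak>  gain %.6g at omega0 = %.6g rad/time%s\n",
              x$gain, x$omega0, if (x$flat) "  [flat response]" else ""))
  invisible(x)
}

#' Near-optimal stimulation signal at the critical frequency
#'
#' The exponentially damped sinusoid `A exp(-eps t) cos(omega0 t)` on
#' `[0, T_active]`, normalized to the requested L2 energy; with `eps = 0`
#' it coincides with the normalized cosine at `omega0` (the two give
#' indistinguishable designs for small `eps`).
#'
#' @param omega0 carrier frequency (rad/time)
#' @param damping decay rate `eps >= 0`
#' @param T_active active horizon; the signal is zero afterwards
#' @param energy target L2 norm
#' @return an [input_signal()] of kind `"damped_cosine"`
#' @export
build_near_optimal_input <- function(omega0, damping = 0.01, T_active, energy = 1) {
  input_signal("damped_cosine", omega = omega0, T_active = T_active,
               energy = energy, damping = damping)
}
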