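# Finite-duration stimulus profiles with exact L2-energy normalization.
#
# Every signal is supported on [0, T_active] and identically zero afterwards
# (experiments end); the amplitude is chosen so that the integral of u^2 over
# the active window equals energy^2 — in closed form where one exists, by
# numeric quadrature otherwise.

.signal_kinds <- c("constant", "sine", "cosine", "damped_cosine",
                   "exp_mod_sine", "square", "sinc", "zero")

#' Construct a stimulus signal of exact L2 energy
#'
#' @param kind one of `"constant"`, `"sine"`, `"cosine"`, `"damped_cosine"`
#'   (damped cosine at the critical frequency, the near-optimal input from
#'   linearized design), `"exp_mod_sine"` (sine with an exponentially
#'   increasing-then-decreasing multiplier), `"square"` (zero-mean square
#'   wave starting at `+amplitude`), `"sinc"` (centered at `T_active/2`),
#'   or `"zero"`
#' @param omega angular frequency in rad/time (periodic kinds)
#' @param T_active active horizon; the signal vanishes for `t > T_active`
#' @param energy target L2 norm over `[0, T_active]`
#' @param damping decay rate for `"damped_cosine"` / `"exp_mod_sine"`
#' @param phase phase offset added to the argument of periodic kinds
#' @return object of class `input_signal`: a list with the vectorized
#'   evaluator `fun(t)`, the amplitude and the construction parameters
#' @export
input_signal <- function(kind, omega = NULL, T_active, energy = 1,
                         damping = NULL, phase = 0) {
  kind <- match.arg(kind, .signal_kinds)
  if (T_active <= 0) stop(validation_error("T_active must be positive"))
  if (kind != "zero" && energy <= 0) stop(validation_error("energy must be positive"))
  periodic <- kind %in% c("sine", "cosine", "damped_cosine", "exp_mod_sine", "square", "sinc")
  if (periodic) {
    if (is.null(omega) || omega <= 0)
      stop(validation_error(paste0("kind '", kind, "' requires omega > 0")))
  }
  Tw <- T_active
  base <- switch(kind,
    zero = function(t) rep(0, length(t)),
    constant = function(t) rep(1, length(t)),
    sine = function(t) sin(omega * t + phase),
    cosine = function(t) cos(omega * t + phase),
    damped_cosine = {
      d <- if (is.null(damping)) 0.01 else damping
      function(t) exp(-d * t) * cos(omega * t + phase)
    },
    exp_mod_sine = {
      d <- if (is.null(damping)) 0.05 else damping
      function(t) exp(-d * abs(t - Tw / 2)) * sin(omega * t + phase)
    },
    square = function(t) ifelse(sin(omega * t + phase) >= 0, 1, -1),
    sinc = function(t) {
      z <- omega * (t - Tw / 2)
      ifelse(abs(z) < 1e-12, 1, sin(z) / z)
    })

  amp <- if (kind == "zero") 0 else {
    e2 <- switch(kind,
      constant = Tw,
      square = Tw,
      sine = Tw / 2 - sin(2 * (omega * Tw + phase)) / (4 * omega) + sin(2 * phase) / (4 * omega),
      cosine = Tw / 2 + sin(2 * (omega * Tw + phase)) / (4 * omega) - sin(2 * phase) / (4 * omega),
      {   # numeric quadrature for the interpretive shapes
        stats::integrate(function(t) base(t)^2, 0, Tw,
                         subdivisions = 2000L, rel.tol = 1e-12)$value
      })
    energy / sqrt(e2)
  }

  fun <- function(t) ifelse(t >= 0 & t <= Tw, amp * base(pmin(pmax(t, 0), Tw)), 0)
  structure(list(kind = kind, omega = omega, T_active = Tw, energy = energy,
                 amplitude = amp, damping = damping, phase = phase, fun = fun),
            class = "input_signal")
}

#' @export
print.input_signal <- function(x, ...) {
  cat(sprintf("<input_signal '%s'>  amplitude %.6g, T_active %g, ||u||_2 = %g%s\n",
              x$kind, x$amplitude, x$T_active, x$energy,
              if (!is.null(x$omega)) sprintf(", omega = %.6g", x$omega) else ""))
  invisible(x)
}

# numerically integrated squared norm of a signal over [0, T_active];
# integrates piecewise between sign switches for the square wave
signal_energy <- function(sig, rel.tol = 1e-10) {
  if (sig$kind == "zero") return(0)
  if (sig$kind == "square") {
    halfper <- pi / sig$omega
    brk <- unique(c(seq(0, sig$T_active, by = halfper), sig$T_active))
    val <- sum(vapply(seq_len(length(brk) - 1), function(i)
      stats::integrate(function(t) sig$fun(t)^2, brk[i], brk[i + 1],
                       rel.tol = rel.tol)$value, 0))
    return(val)
  }
  stats::integrate(function(t) sig$fun(t)^2, 0, sig$T_active,
                   subdivisions = 5000L, rel.tol = rel.tol)$value
}
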