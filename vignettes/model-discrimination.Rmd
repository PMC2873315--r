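---
title: "Designing maximally discriminating experiments for rival ODE models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing maximally discriminating experiments for rival ODE models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discrimODE)
```

## The discrimination problem

Two ODE models of the same biochemical system,

$$\dot x_i = f_i(x_i) + g_i(x_i)\,u, \qquad y_i = h_i(x_i), \qquad i = 1,2,$$

are *rivals* when both reproduce all data collected so far.  Because they
describe the same experiments, they share the measured output dimension,
the input channels, and — after a change of coordinates that places the
investigated steady state at the origin of each model — the same resting
output, $h_1(0) = h_2(0)$.  The package assumes this steady state is
asymptotically stable in both models (this is checked, and violated models
are refused), and that inputs act for a finite time window only, since real
experiments end.

Concatenating the two models gives the *difference system* with state
$(x_1, x_2)$ and output $y = y_1 - y_2$, which vanishes identically when
both models are started at rest and driven by nothing.  An experiment is a
perturbation of bounded size — an initial state, a stimulus of unit energy,
or a settable-parameter change — and the design goal is to maximize
$\lVert y_1 - y_2\rVert_2$, the $L_2$ norm of the output difference over
the whole transient.  A large designed difference means even noisy
measurements can invalidate one rival.

## Initial-condition design

With $u = 0$ and a common perturbation $x_1(0) = x_2(0) = \beta v$,
$\lVert v\rVert = 1$, the linearized difference system has output energy

$$\int_0^\infty y^\top y\,dt = x(0)^\top P\, x(0), \qquad
  A^\top P + P A + C^\top C = 0,$$

with $P$ the observability gramian.  Substituting the common perturbation
restricts $P$ to $R = P_{11} + P_{12} + P_{21} + P_{22}$ (blocks of size
$n$), and the optimal direction is the unit top eigenvector of $R$
(`observability_gramian()`, `optimal_common_initial_direction()`).  Eigen
ties are resolved deterministically: the full top eigenspace is returned
with a flagged tie, plus the representative with lexicographically greatest
leading component; the sign convention makes the first nonzero component
positive.

For the nonlinear system the package constructs a polynomial *storage
function* $S \ge 0$, $S(0) = 0$, whose dissipation inequality
$-\nabla S \cdot f - h^\top h \ge 0$ holds on a region
$D = \{\lVert x_1\rVert \le \alpha,\ \lVert x_2\rVert \le \alpha\}$ around
the steady state.  Integrating it along trajectories gives
$\lVert y\rVert_2^2 \le S(x(0))$ for starts inside the certified level
set.  The design then shrinks the level sets of the common-state
restriction of $S$ until they touch the sphere of radius $\beta$; the
touching point — recovered from the dual moment matrix of that second
programme, with a multi-start sphere search as fallback — is the nonlinear
design (`storage_for_ic_design()`, `extract_optimal_ic()`).

Among all feasible storage functions we select the one minimizing the trace
of the quadratic part of $S$ at the origin, which makes level sets large;
for a linear system this recovers the observability gramian exactly, a
property the test suite exploits as an oracle.

## Input design

For stimuli of unit $L_2$ energy the linearized theory is cleanest in the
frequency domain: the achievable output norm is governed by the Bode
magnitude of $G(j\omega) = C(j\omega I - A)^{-1}B$ (largest singular value
for multi-output selections), and the best narrow-band stimulus sits at the
*critical frequency* $\omega_0$ where it peaks.  `frequency_peak()` scans a
logarithmic grid over $[10^{-3}, 10^3]$ rad per model time unit (2000
points) and refines the peak by golden-section search to relative width
$10^{-6}$; the four printed digits of the case study's critical frequencies
motivated that resolution.  A response flat to within $10^{-8}$ relative is
flagged rather than silently argmaxed.

The stimulus library (`input_signal()`) holds constant, sine, cosine,
damped-cosine (the near-optimal input from linearization, with default
damping 0.01 — small enough that it is indistinguishable from the cosine),
exponentially-modulated sine, square-wave and sinc shapes, all supported on
$[0, T_\text{active}]$ and exactly normalized: closed-form amplitudes where
they exist (constant $\varepsilon/\sqrt{T}$, sine/cosine/square from their
antiderivatives), numeric quadrature otherwise.  Conventions the source
problem leaves open are configurable and documented: the square wave starts
at $+$amplitude with period $2\pi/\omega_0$; the sinc is centered at
$T_\text{active}/2$; the exponential modulation peaks at the window
midpoint with default decay 0.05.

Candidate stimuli are ranked by the *nonlinear simulated* norm, not the
linear prediction — the linearization only chooses the frequency.  The SOS
route supplies the complementary guarantee: a storage function with
$-\nabla S\cdot(f + gu) - y^\top y + \gamma\, u^\top u \ge 0$ on $D$
certifies $\lVert y\rVert_2^2 \le \gamma \lVert u\rVert_2^2$, so
$\sqrt{\gamma}$ (reported as `gain`) bounds every unit-energy experiment.
$\gamma$ enters the semidefinite programme linearly and is minimized
directly.  Whether trajectories remain inside $D$ under a given stimulus is
*assumed*, not certified (a reachability analysis is out of scope); the
bound-versus-simulation property is nevertheless confirmed on a library of
stimuli in the test suite.

## Structural design

Here the experimenter may also fix parameters $p$ (total protein levels,
rate constants) anywhere in a box $\Pi = \prod_j [a_j, b_j]$ before the
experiment.  The steady state moves with $p$, so the package solves it
*symbolically* by sequential linear elimination — at each pass one
steady-state equation that is linear in one remaining state is solved for
it — yielding rational expressions in $p$ that are validated against the
numeric root solver to $10^{-8}$ on a box grid.  The shifted drift is then
rational in $p$ with a denominator that is checked positive on the box and
cleared against the dissipation inequality, keeping the programme
polynomial.  Models outside this structure are refused with a clear error
rather than approximated.

The parametric storage function $S(x, p)$ — quadratic in the states with
polynomial parameter dependence, jointly SOS — satisfies the dissipation
inequality on $D \times \Pi$, with ball multipliers on the states and box
multipliers $(p_j - a_j)(b_j - p_j)$ on the parameters.  Its objective
minimizes the full Gram trace of $S$: penalizing only the
parameter-independent part leaves the $p$-dependent quadratic mass
unconstrained and misleads the subsequent extraction.  The extraction
programme maximizes $S((v, v), p)$ over the design sphere and the box;
directions are read off the second-order dual moment block (the objective
is even in $v$, so first moments vanish by symmetry), parameter values off
the first-order moments, with a multi-start box-constrained search as
fallback and cross-check.  A deterministic grid search
(`brute_force_structural_search()`), which re-solves and re-shifts the
steady state at every parameter point, serves as the independent
simulation oracle; the two routes are compared whenever
`design_structural(method = "all")` runs.

## Simulation and norms

All trajectories are integrated with `deSolve`'s `lsoda` (stiffness-aware,
default relative tolerance $10^{-9}$), with the squared output difference
accumulated as an extra state so the energy is integrated at full solver
accuracy.  The horizon starts at $T_\text{active} + 10/|\mathrm{Re}\,
\lambda_\text{slow}|$ and is extended by 50% until the tail estimate — the
linearized observability-gramian energy of the final state — drops below
$10^{-6}$ of the total, approximating the integral to infinity.  Square
waves are integrated with a step cap of a quarter half-period so switches
are not stepped over, and the stimulus window boundary is an integration
breakpoint.  Reported norms change by less than $10^{-4}$ when tolerances
are halved (checked in the tests).

## The semidefinite solver

No SDP backend exists in the surrounding R stack, so the package includes
one designed for exactly the programmes it generates: a first-order
operator-splitting (ADMM) method on the homogeneous self-dual embedding,
with zero/nonnegative/PSD cones, Ruiz equilibration (cone-uniform on PSD
blocks), over-relaxation, and restarted Anderson acceleration.  It returns
a primal/dual pair or a certificate of infeasibility/unboundedness; dual
equality multipliers double as the moment sequences the extraction step
needs.  Two structural reductions proved essential in practice:

* **Origin facial reduction.**  The dissipation identity vanishes on the
  subspace $x = 0$, which forces the constant (and generally any
  state-free) monomials of every Gram and multiplier basis to have zero
  diagonal.  Removing them restores strict feasibility; leaving them in
  stalls any first-order method.
* **Diagonal-consistency basis pruning.**  A Gram basis monomial whose
  square lies outside the constraint support (and is not reachable as a
  cross product of other basis elements) has a forced-zero diagonal; such
  monomials are pruned to a fixed point before assembly.  This is how the
  input variable keeps exactly its linear basis element in the gain
  programme.

States are rescaled by $\alpha$ (and inputs likewise, and parameters to
$[-1,1]$) before assembly so all coefficients are $O(1)$; certificates are
mapped back symbolically.  Every returned certificate is re-verified
independently of the solver: the identity residual is absorbed into the
main Gram matrix and all Gram blocks are re-checked for positive
semidefiniteness by eigendecomposition, with the residual and minimum
eigenvalues reported on the certificate object.

Solver tolerances default to $10^{-6}$ for storage construction and the
extraction programmes, $5\times10^{-6}$ for the gain bound and
$2\times10^{-5}$ for the eight-variable parametric programme — the level
sets and bound values these programmes feed into are insensitive at those
residuals, and the independent re-verification reports the achieved
quality in any case.

## Defaults and their rationale

| parameter | default | why |
|---|---|---|
| region radius `alpha` | 0.1 (state units) | physical feasibility bound of the response-regulator coordinate in the case study; the region must exclude meaningless states |
| design magnitude `beta` | 1 | unit-norm perturbations, as in the case study; level-set containment of `beta` in the certified region is optional and off by default, matching practice |
| storage degree `deg_S` | 2 | recovers the gramian in the linear limit; degree 4 available, never improves the certified gain (monotonicity is tested) |
| stimulus window `T_active` | 60 time units | the case study's stimulation window |
| frequency grid | 2000 points on $[10^{-3}, 10^3]$, refined to $10^{-6}$ | four-digit critical frequencies |
| integrator | `lsoda`, rtol $10^{-9}$ | stiffness robustness; tail below $10^{-6}$ of total energy |
| brute-force grids | 300-point Fibonacci sphere (IC), $5\times5$ box $\times$ 60 directions (structural), with local refinement | resolves the case-study optimum within printed precision at desktop runtimes |

## What passing tests do and do not show

The shipped rivals are deliberately small (three states each, bilinear
nonlinearity, shared steady state by construction).  They exercise every
code path — rational parameter shifts, slow/fast mode separation, sign-odd
nonlinear responses — but real models bring features the fixtures do not:
measurement noise (not modelled; the whole point of maximizing the
difference is robustness to it), rational (Michaelis-Menten) vector
fields, which the simulation and linear routes accept but the SOS engine
refuses by design, non-shared steady states, and dimensions at which the
eight-variable SOS programme here would grow beyond first-order-solver
comfort.  The package reports solver status and certificate quality
precisely so that such cases degrade loudly, not silently.

## Known limitations

* The SOS path requires polynomial vector fields; denominators are cleared
  only for the parametric steady-state shift, not for rational kinetics.
* Trajectory containment in the certified region under stimulation is
  assumed, not proven.
* The built-in SDP solver is a first-order method: certificates carry
  residuals around $10^{-6}$–$10^{-5}$, not interior-point accuracy; the
  independent re-verification quantifies this on every certificate.
* Structural designs are only as good as the parametric storage function;
  the grid oracle should always be run alongside (`method = "all"`), and
  is, in the validation suite.
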