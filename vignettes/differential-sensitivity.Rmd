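---
title: "Differential sensitivity methods in diffsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential sensitivity methods in diffsens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffsens)
```

# The problem

Biological dynamical models — tumour–immune interaction, epidemic spread,
branching populations — are fitted with parameters known only imprecisely.
The differential sensitivity of an output $Q(\theta)$ is its gradient at
the estimated parameters. This vignette documents how each engine in
**diffsens** computes such gradients, the assumptions each one makes, the
numerical defaults and why they were chosen, and what the accompanying
tests do and do not establish.

# Derivative engines

## Complex perturbation

For a function $g$ that is *analytic* in $\theta$ — expandable in a
convergent power series, which holds whenever the implementation uses only
arithmetic, powers, `exp`, `log`, `sin`, `cos`, `sqrt` and no branches on
parameter values — the imaginary Taylor expansion gives

$$g'(\theta) = \mathrm{Im}\, g(\theta + i\Delta)/\Delta + O(\Delta^2).$$

No two nearby real numbers are subtracted, so there is no cancellation:
$\Delta$ can be made as small as $10^{-12}$ and the error reaches the
machine-precision floor. `cs_jacobian()` applies this per parameter;
columns are independent, and the result is invariant to the order in which
they are evaluated. The default $\Delta = 10^{-12}$ sits at the bottom of
the useful band; any value in $[10^{-10}, 10^{-13}]$ gives
indistinguishable first derivatives in double precision, and a per-call
override is provided. With `relative = TRUE` coordinate $j$ is perturbed
by $\theta_j\Delta i$ instead — useful when parameters span many orders of
magnitude, as in the CARRGO model where rates range from $10^{-11}$ to
$10^9$. A coordinate that is exactly zero falls back to the absolute step:
a relative step of zero would produce $0/0$, and no other convention is
defensible for a parameter with no scale.

## Second derivatives

Pure second partials use the rotated step $e^{i\pi/4}\Delta$:

$$\partial^2_j g = \mathrm{Im}\big[g(\theta + e^{i\pi/4}\Delta e_j)
  + g(\theta - e^{i\pi/4}\Delta e_j)\big]/\Delta^2 + O(\Delta^4).$$

Mixed partials perturb the *pair* $(e_j + e_k)$ the same way; the
imaginary sum equals $\partial^2_j g + \partial^2_k g + 2\partial_j
\partial_k g + O(\Delta^4)$, so `cs_hessian()` computes all diagonal
entries first, then subtracts them from each pair evaluation and halves
the remainder. Both $(j,k)$ and $(k,j)$ are assigned, making the returned
matrix exactly symmetric by construction. Because a sum of two
evaluations appears, roundoff is no longer absent: the total error model
is

$$\mathrm{err}(\Delta) \approx C_1\Delta^4 + C_2\,\varepsilon|g|/\Delta^2,$$

with $\varepsilon \approx 2\times10^{-16}$. The two terms balance near
$\Delta \approx 10^{-2}$–$10^{-3}$; below that the $\varepsilon/\Delta^2$
floor dominates, which is why the default is $\Delta = 10^{-4}$ (errors
$\sim 10^{-8}$ relative on unit-scale functions) and why the test suite
asserts the $\Delta^4$ scaling only at the truncation-dominated end of
the band while bounding the error uniformly (below $10^{-5}$ relative)
across $\Delta \in [10^{-3}, 10^{-5}]$. Asserting a pure $\Delta^4$ law
at $\Delta = 10^{-5}$ would require a vacuously large constant in double
precision.

## Finite differences and dual numbers

Forward differences (`fd_jacobian`) have error $O(\Delta) +
O(\varepsilon/\Delta)$, optimal near $\sqrt\varepsilon$; central
differences (`cd_jacobian`) have $O(\Delta^2) + O(\varepsilon/\Delta)$,
optimal near $\varepsilon^{1/3}$. Both are cancellation-limited, which
the tests exhibit as a U-shaped error curve — the contrast with the
complex step is the point.

`dual_jacobian` is a minimal forward-mode automatic-differentiation
engine: a carrier holding a value and a matrix of partials, one column
per seeded direction, with the product/chain rules implemented for the
elementary operations. Seeding `chunk` unit directions per pass trades
passes against carrier width without changing the result (the tests
assert bit-identical Jacobians across chunk sizes). The carrier
propagates first-order partials only; Hessians by nested duals are
deliberately not implemented, since the rotated complex step already
covers second order with less machinery. Unsupported operations
(comparisons, `tan`, rounding) raise an error naming the operation rather
than silently returning a wrong derivative.

# Trajectory sensitivities

## Forward sensitivity equations

Differentiating $\dot x = f(x, \beta)$ in $\beta$ and exchanging
derivative order gives the augmented system

$$\dot S = (\partial f/\partial x)\,S + \partial f/\partial \beta,
  \qquad S(t_0) = 0,$$

integrated jointly with the states (`forward_ode_sensitivities`). The
local Jacobians are evaluated by complex step on the right-hand side at
each solver step (a dual-number option and a user-supplied analytic
Jacobian are available); the initial condition is parameter-independent
by assumption, so $S$ starts at zero. A `directions` matrix selects the
Jacobian-free directional variant, propagating only $Sv$ for chosen
directions — worthwhile when parameters are many; the bundled models are
small, so the default builds full Jacobians.

## Complex-step trajectory sensitivities

`cs_ode_sensitivities` re-solves the ODE once per parameter with
$\beta_j + i\Delta$ over the complex field and divides the imaginary part
of the saved states by $\Delta$. The integration uses `deSolve::zvode`
with BDF and an internally generated Jacobian (`mf = 22`): the non-stiff
Adams option stalls at its step cap during sharp transients such as the
CARRGO population crash, while BDF handles both the stiff Robertson
system and the non-stiff models with negligible overhead at these sizes.
An equivalent formulation that stacks real and imaginary parts into a
doubled real system integrated by `lsoda` is available as
`integrator = "split"`; the two agree within solver tolerance and the
tests enforce that contract. The unperturbed trajectory comes from a
plain real solve, and the real part of any perturbed solve must (and is
tested to) reproduce it within tolerance.

Solver defaults: save grid spacing 1 time unit; relative tolerance
$10^{-5}$ for non-stiff models and $10^{-7}$ for the stiff Robertson
system; absolute tolerance $10^{-3}\,\mathrm{rtol}$, tightened further in
studies whose states span many scales.

## Second-order trajectory sensitivities

`second_order_ode_sensitivities` treats the whole solve map
$\beta \mapsto x(t,\beta)$ as the target of the rotated-step formulas:
each function evaluation is one complex ODE solve, so filling a Hessian
over $p$ parameters costs $1 + 2p + p(p-1)$ solves plus the first-order
ones. The SIR prediction study ($p = 2$, 100 days) is seven solves and
runs in well under a second.

## Adjoint gradients

For a scalar functional $g[x(T,\beta), \beta]$, `adjoint_gradient`
implements the standard continuous adjoint: solve forward once, then
integrate the costate backwards from $\lambda(T) = \partial g/\partial
x(T)$ via $\dot\lambda = -(\partial f/\partial x)^\top\lambda$,
accumulating $\int_0^T \lambda^\top \partial f/\partial\beta\,dt$ jointly,
and add the explicit $\partial g/\partial\beta$. The cost is one forward
and one reverse solve regardless of $p$ — $O(n+p)$ against the forward
method's $O(np)$. The reverse pass needs $x(t)$ at arbitrary times, which
is provided by spline interpolation of a dense forward save
(`dense_n = 2001` points by default; studies over 1000 days use more).
The formulation is validated against the forward method rather than
against any printed adjoint system, and the tests require agreement to
$10^{-3}$ relative on well-conditioned functionals.

One caveat the tests document: a functional can be *degenerate*. The
CARRGO cancer compartment is extinct to machine precision
($\sim 10^{-22}$ cells) by day 500 under the default parameters, so the
parameter gradient of $x(1000)$ sits below solver noise and no relative
comparison between engines is meaningful there. The validation
functionals are the cancer count at day 200 (growth phase) and the
CAR T-cell count at day 1000.

# Bundled models

* **CARRGO** (tumour–immune): $\dot x = \rho x(1 - y/\gamma) -
  \kappa_1 xy$, $\dot y = \kappa_2 xy - \theta y$; rates per day, cell
  counts absolute; $\kappa_1 = 6\times10^{-9}$, $\kappa_2 =
  3\times10^{-11}$, $\theta = 10^{-6}$, $\rho = 0.06$, $\gamma = 10^9$,
  from $(1.25\times10^4, 6.25\times10^2)$ cells over 1000 days. The
  logistic brake divides the *predator* count by the carrying capacity in
  this default form; the conventional form with the brake on the prey,
  $\rho x(1 - x/\gamma)$, is available via `logistic_in_x = TRUE` and
  produces the classic boom–crash trajectory. Both forms are kept because
  the two conventions appear side by side in the literature on this
  model and the choice materially changes the early dynamics.
* **SIR**: $\dot S = -\eta IS/N$, $\dot I = \eta IS/N - \delta I$,
  $\dot R = \delta I$; $\eta = 0.7194$/day (infection rate per
  encounter), $\delta = 0.5025$/day (recovery). $N$ is a fixed constant,
  not a sensitivity parameter (opt-in via `include_N`), defaulting to the
  US-scale $3.4\times10^8$. For small-population demonstrations the
  constant must be set to the actual population: with $S_0 = 1000$ and
  $N = 3.4\times10^8$ the force of infection is $\sim 10^{-5}$/day and no
  epidemic occurs, so the prediction experiment below uses
  $N = S_0 + I_0 = 1010$.
* **ROBER**: the canonical Robertson kinetics
  $(p_1, p_2, p_3) = (0.04, 3\times10^7, 10^4)$ from $(1, 0, 0)$ —
  the standard stiff benchmark; components sum to one, and that
  conservation must transfer to every sensitivity sheet (tested).

# Taylor prediction of perturbed trajectories

Given sensitivities at $\beta$, a nearby trajectory is predicted as
$x(\beta + v) \approx x(\beta) + Sv$ (first order) or
$+\ \tfrac12 v^\top H v$ (second order). The experiment
(`taylor_experiment`) perturbs every parameter multiplicatively,
$\theta_i(1 + U_i)$ with $U_i \sim \mathrm{Uniform}(-m, m)$, re-solves,
and reports normalized error norms. The normalization divides the
Euclidean (Frobenius) norm of the difference by the entry count for
vectors and by its square for matrices; a root-mean-square alternative
(`"sqrt_count"`) is selectable, since published error tables rarely state
which convention they used and the *ordering* of first versus second
order — the scientifically meaningful output — is invariant to it. At
$m = 0.25, 0.15, 0.05$ the second-order error is smaller on every
compartment and the ratio err2/err1 shrinks with $m$, the expected
$O(m^3)$ versus $O(m^2)$ behaviour.

# The stochastic SIR chain

The Markov chain on (infectives $i$, survivors $n$) with recovery rate
$i\delta$ and infection rate $i(n-i)\eta/N$ yields, by first-step
analysis, triangular recurrences for the mean time to elimination and
mean total ever infected, with boundary rows $t_{0n} = m_{0n} = 0$,
$m_{ii} = i$, $t_{ii} = \sum_{j\le i} 1/(j\delta)$. The sweep order —
$n$ ascending, $i$ descending within a column — is forced by the data
dependencies ($t_{i+1,n}$ must precede $t_{i,n}$). The inner loop is
compiled; full $(N+1)^2$ grids are kept for inspection up to $N = 8000$,
beyond which memory (two grids of $(N+1)^2$ doubles) forces the streaming
two-column mode, which is how the population-34 001 study runs in
seconds.

Sensitivities come from two independent engines: complex perturbation of
$\delta$ or $\eta$ through the whole sweep (step $10^{-10}$), and a
manual tandem sweep propagating the quotient-rule derivatives of
$a = i\delta$, $b = i(n-i)\eta/N$, $1/(a+b)$ with differentiated boundary
rows. They agree entrywise to $\sim10^{-10}$ relative at $N = 100$ in
practice; the tests require $10^{-6}$. A dense linear-system solution of
the exact first-step equations validates the sweep itself for tiny $N$,
and an exact Gillespie simulator (direct method, R's RNG, seeded)
provides the statistical check at scale.

One property worth recording: the mean extinction time is *not* monotone
in the number of initial infectives at fixed $n$ — an extra infective
also means one fewer susceptible, so beyond a few initial cases the
remaining epidemic is shorter. Mean total infections are monotone, and
extinction time is monotone whenever the infection channel is off.

# Birth–death–migration branching processes

On $n$ nodes with birth $\beta_i$, death $\delta_i$ and migration
$\lambda_{ij}$, the mean generator has $\Omega_{ii} = \beta_i - \delta_i -
\lambda_i$ and $\Omega_{ij} = \lambda_{ij}$; $e^{t\Omega}$ propagates
expected counts (`Matrix::expm`). For an irreducible (strongly connected)
migration graph, $\Omega$ is an irreducible Metzler matrix, so its
eigenvalue of maximal real part $\rho$ is real and simple with a positive
right eigenvector — that is the selection rule `dominant_eigen` uses,
normalizing $w > 0$ first and then $vw = 1$ (the normalization determines
the sensitivity formula; positivity of $w$ resolves the remaining sign
freedom). Reducible graphs are refused with advice to analyse components
separately, since the dominant eigenvalue may then be complex or
non-simple and per-component analysis is the meaningful decomposition.

Sensitivities:

* growth rate: $\partial\rho/\partial\theta = v(\partial\Omega/
  \partial\theta)w$ with elementary structure matrices — so
  $\partial\rho/\partial\delta_i = -\partial\rho/\partial\beta_i$
  *exactly*, an identity the tests assert without tolerance;
* extinction: the minimal fixed point of the offspring generating
  function is found by iterating from $\mathbf 0$ (monotone,
  nondecreasing, bounded); defaults 500 iterations, stop when successive
  iterates differ by less than $10^{-16}$. Hitting the cap sets
  `converged = FALSE` rather than erroring, because near-critical
  processes converge geometrically slowly and a flagged partial answer is
  more useful than an exception. Implicit differentiation
  $d_\theta e = [I - d_eP]^{-1} d_\theta P$ requires strict
  supercriticality ($\rho > 0$, checked): at or below criticality
  $e = \mathbf 1$ and $I - d_eP(\mathbf 1)$ is singular; the error
  message points near-critical users to complex-step differentiation of
  the fixed point instead;
* total progeny: $A = (I-F)^{-1}$ for subcritical processes (spectral
  radius of $F$ checked), $d_\theta A = A(d_\theta F)A$ with the quotient
  rule on the normalizers.

Parameters pack as $(\delta_{1..n}, \beta_{1..n}, \mathrm{vec}\,\lambda)$
column-major throughout, diagonal $\lambda$ slots carried as structural
zeros so index arithmetic stays uniform.

# Random fixtures: what they emulate and what they do not

`random_bdm` draws rates uniformly on $\beta \in [0.05, 0.16]$,
$\delta \in [0.05, 0.19]$, $\lambda \in [3\times10^{-4},
4.6\times10^{-4}]$ — slow per-capita dynamics with migration two to three
orders of magnitude weaker, the regime of early epidemic spread across
weakly coupled locations. Criticality is imposed by offsetting
$\delta = \beta \pm 0.03$, giving unambiguously sub- or supercritical
processes. `perturb_params` emulates parameter uncertainty as independent
multiplicative errors of bounded relative size. Passing tests on these
fixtures establishes that the analytic sensitivity formulas agree with
independent differentiation of the primal computations across the rate
regime — it does not establish anything about strongly coupled networks
($\lambda \sim \beta$), near-critical processes, heavy-tailed parameter
uncertainty, or model misspecification, none of which the generators
produce.

# Problem sizes and determinism

The test suite runs the epidemic-scale chain at $N = 34001$ (the
streaming sweep, a few seconds), the cross-engine ODE studies over 1000
days at save spacing 1, the Gillespie checks at 100–1000 runs, and 50
random branching fixtures; the whole suite completes in well under a
minute on one core. Every stochastic component (simulator, perturbation
draws, fixtures) is driven by an explicit seed, and all engines are
deterministic given their inputs.

# Known limitations

* Complex-step engines require analyticity; models with absolute values,
  thresholds or lookup tables need the dual-number or finite-difference
  engines, and the dual carrier covers first order only.
* Sensitivities are local; no global (sampling-based) sensitivity
  analysis is provided.
* Sensitivity with respect to initial conditions is not implemented (the
  initial state is treated as parameter-independent).
* The adjoint implementation interpolates the forward solution rather
  than checkpointing; extremely long or extremely stiff horizons would
  need denser saves.
* The SIR chain recurrences return means only, not variances or higher
  moments; extinction-time distributions come from the simulator.
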