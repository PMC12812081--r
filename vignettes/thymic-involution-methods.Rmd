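---
title: "Methods: optimal naive T cell production schedules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimal naive T cell production schedules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thymodel)
```

## The model and its assumptions

The thymus exports new naive T cell clones at an age-dependent rate $h(t)$;
the peripheral repertoire diversity, counted as number of clones $N(t)$,
obeys $dN/dt = h - uN$ with peripheral decay rate $u$. A host is exposed to
$n$ pathogen strains, each arriving as an independent Poisson process with
per-strain encounter rate $f$. Immune memory is perfect and lifelong, so a
strain with rate $f$ is still novel at age $t$ with probability $e^{-ft}$,
and the expected rate of novel encounters per strain is

$$g(t) \;=\; \mathbb{E}\!\left[f\,e^{-ft}\right],$$

the *novelty-weighted encounter intensity*. Meeting a novel strain costs
$K/N$ — the thinner the repertoire, the longer a pathogen proliferates
before a matching clone responds — and sustaining production costs $m\,h$.
The instantaneous cost rate is therefore
$\Psi(t) = n\,g(t)\,K/N(t) + m\,h(t)$.

Everything in the package follows from two optimization readings of this
trade-off: pointwise minimization of $\Psi$ when peripheral turnover is
fast, and maximization of $\phi = C - \int_0^T \Psi\,dt$ subject to the ODE
and $0 \le h \le h_{\max}$ in general.

Key modeling assumptions, inherited by every result:

* clone *number*, not cell number, carries the benefit — peripheral
  proliferation does not create diversity;
* the fighting cost is exactly inversely proportional to $N$ (the simplest
  declining form);
* encounters are independent across strains and hosts; re-encounters are
  free (perfect memory);
* within-infection dynamics are compressed into the single constant $K$.

## Parameters

| symbol | meaning | units | notes |
|---|---|---|---|
| $n$ | strains met over a lifetime | count | presets use 1000 |
| $f,\ \bar f$ | per-strain encounter rate, its mean | 1/age | e.g. 0.1–0.3/yr |
| $K$ | fighting cost magnitude | cost | only $K/m$ matters for shapes |
| $m$ | production cost per unit output | cost·age/cell | numeraire, presets use 1 |
| $u$ | peripheral clone decay rate | 1/age | controls the phase structure |
| $h_{\max}$ | production cap | cells/age | binds only near birth |
| $T$ | maximum age | age | horizon of the control problem |
| $C$ | baseline fitness | fitness | additive; default 0 |

The quasi-static schedule depends on the parameters only through the
product $K u n / m$ (its square root scales the schedule) and through the
distribution of $f$. The quasi-static presets therefore fix
$K u n/m = 10^4$ and decompose it as $n = 1000, m = 1, u = 1, K = 10$; any
other decomposition gives identical tables.

## Quasi-static optimum

With fast turnover, $N \approx h/u$ and minimizing
$\Psi(h) = n g K u/h + m h$ at each age gives
$h^\ast(t) = \sqrt{K u n\, g(t)/m}$, where the two cost components are
exactly equal (the usual $a/x + bx$ balance). Closed forms for $g$:

* identical rates: $g = \bar f e^{-\bar f t}$, so
  $h^\ast \propto e^{-\bar f t/2}$ — exponential involution at *half* the
  encounter rate;
* Gamma-distributed rates (shape $a$, rate $b$, mean $\bar f = a/b$):
  $g = \bar f (1+\bar f t/a)^{-(a+1)}$, so
  $h^\ast \propto (1+\bar f t/a)^{-(a+1)/2}$, a power law for small $a$;
* lognormal and empirical rates: numerical expectation (below).

Because $g$ is a mixture of exponentials, $\log h^\ast$ always has negative
slope and nonnegative second derivative, with zero curvature exactly in the
single-rate case — `log_schedule_diagnostics()` checks this on finite
differences with a $10^{-10}$ dead band for floating-point noise. Lifetime
production $\int h^\ast dt$ has the closed form
$2\sqrt{Kun/(m\bar f)}$ for identical rates on an infinite horizon; for
Gamma shapes $a \le 1$ the infinite-horizon integral diverges and
`lifetime_production()` reports an error rather than a silently truncated
number, since the model itself never evaluates that case.

One printed-source discrepancy is resolved here once: the dispersion-ladder
examples state their common mean as "$b/a = 0.1$" with $a = 100, b = 1000$,
while the distribution's mean is $a/b$ — only $a/b$ yields 0.1, so the
package defines `mean_rate = shape/rate_param` and treats the other
expression as a typo.

## Dynamic optimum via the Maximum Principle

The Hamiltonian is linear in $h$ with coefficient $\lambda - m$, where the
costate $\lambda(t)$ (marginal fitness of one extra clone) solves
$\dot\lambda = -K n g/N^2 + u\lambda$, $\lambda(T) = 0$. Hence bang-bang
logic — $h = h_{\max}$ where $\lambda > m$, $h = 0$ where $\lambda < m$ —
with a possible singular arc where $\lambda \equiv m$. On the arc the
costate equation pins the state to

$$N^\ast(t) = \sqrt{K n\, g(t) / (u m)},$$

identical to the quasi-static clone count, and the arc control is
$h^\ast = \dot N^\ast + u N^\ast = N^\ast\,(u + g'/2g)$. This general
stationarity form reduces exactly to the printed single-rate and Gamma
closed forms and extends the construction to lognormal/empirical models,
for which no closed form exists. The arc is infeasible (negative control)
when $u \le \bar f/2$: slow peripheral decay concentrates all production at
the start of life.

The candidate schedule is assembled from two switching ages:

* $t_1$: the maximum-rate trajectory
  $N(t) = N_0 e^{-ut} + (h_{\max}/u)(1 - e^{-ut})$ meets $N^\ast(t)$;
  solved by a coarse sign scan (1000 points) plus bracketed `uniroot` at
  $10^{-12}$ tolerance. Once the trajectory is on the arc the cap can no
  longer bind, because $h^\ast < u N^\ast < h_{\max}$ there.
* $t_2$: integrating $\lambda$ backward from $\lambda(T)=0$ through the
  no-production tail, $\lambda$ reaches $m$. Identical rates give
  $T - t_2 = \log(2 - \bar f/u)/(u - \bar f)$, implemented with `log1p` and
  an exact $1/u$ branch at the removable singularity $u = \bar f$;
  dispersed-rate models solve the equivalent integral condition
  $u\int_{t_2}^{T} (g(s)/g(t_2))\,e^{u(s-t_2)}ds = 1$ by root finding.

If $t_1 < t_2$ the schedule is three-phase; otherwise the singular segment
vanishes and the single switch $t_3$ of the bang-bang schedule is the root
of $\lambda(t_3) = m$ on the self-consistent trajectory — the Maximum
Principle's switching condition applied at the jump, and numerically the
same age a dense fitness scan over $t_3$ selects (`two_phase_scan()`
cross-checks this to within one grid step). The second-order
Legendre–Clebsch requirement on the arc is verified *numerically*: the
certificate estimates $\partial/\partial h$ of the second time derivative
of $\partial H/\partial h$ by central differences (its analytic value is
$2Kng/N^3 > 0$) and requires a positive sign; no symbolic proof is
attempted.

## Numerical choices

* **Linear-ODE propagation instead of a generic solver.** No ODE-solver
  package is available in the target environment, but both ODEs are linear,
  so the integrator uses exact integrating-factor steps,
  $N(t_{k+1}) = N_k e^{-u\Delta} + \int e^{-u(t_{k+1}-s)}h(s)\,ds$, with
  7-point Gauss–Legendre for the inhomogeneous terms (3-point chains inside
  subintervals of smooth non-constant controls); constant-control steps are
  exact. The costate runs backward the same way. Phase boundaries are exact
  grid points, so control discontinuities are never smeared. On the
  singular arc this machinery reproduces $\lambda = m$ to $10^{-14}$
  relative.
* **Base grid.** 1200 subintervals over $[0,T]$ (a `control_problem`
  field), refined geometrically near $t = 0$ down to the scale $N_0/h(0)$
  where the fighting-cost integrand behaves like $1/(N_0 + ht)$.
* **Initial-state regularization.** The model's own $N(0) = 0$ makes
  $\int K n g/N$ diverge for every schedule; fitness is evaluated from
  $N_0 = 10^{-6} N^\ast(0)$ by default, applied identically to all compared
  schedules. Rankings are insensitive to $N_0$; absolute $\phi$ values are
  not, and are reported only under this convention.
* **Lognormal expectations.** Gauss–Hermite quadrature in $z = \log f$ with
  128 nodes and a doubling check at tolerance $10^{-8}$ (64 nodes leave
  $\sim10^{-7}$ residuals at large $t\sigma^2$; 128 is converged to
  $\sim10^{-11}$).
* **Direct optimizer.** Piecewise-constant controls (default 200 intervals),
  exact adjoint gradient $\partial\phi/\partial h_j = \int_{I_j}(\lambda-m)dt$
  evaluated from the identity
  $\int\lambda = (\Delta\lambda + \int A)/u$, and box-constrained L-BFGS-B
  from multiple random starts (default 8; the first start is the flat
  schedule $h_{\max}/2$). The gradient matches central finite differences to
  $\sim10^{-9}$ relative, and the optimizer reproduces the analytic
  fitness to $\sim10^{-5}$ relative — well inside the 0.1% equivalence the
  tests demand — without using any Maximum-Principle structure.
* **Degenerate inputs.** $h \le 0$ in the pointwise cost, infeasible
  singular arcs, non-crossing initial phases, horizons too short for a
  final phase, and divergent lifetime integrals are all explicit errors
  with actionable messages, not silent fallbacks; single-phase degenerate
  horizons return with a warning.

## What the simulator emulates — and what it does not

`simulate_lifetime_cost()` draws, per host, each strain's first-encounter
age as an exponential time (truncated at $T$), charges $K/N(\text{age})$
per first encounter along the deterministic $N(t)$, and adds the
deterministic production cost. It validates the expectation structure of
the cost functional: the Monte Carlo mean converges to $\int\Psi\,dt$ at
the $1/\sqrt{\text{hosts}}$ rate. Per-strain rates are resampled per host
for dispersed models by default; `freeze_rates = TRUE` fixes one rate
vector across hosts, matching the fixed-list reading of the cost sum. The
simulator does *not* model within-infection dynamics, pathogen load,
imperfect or waning memory, density-dependent peripheral decay, or
feedback from infections onto $N$ — a green test therefore establishes
internal consistency of the cost model, not immunological realism.

## Design choices where the source was open

* The dynamic worked examples print no $u$; it is a required input
  everywhere, and the regression fixtures pin $u = 1$ (an implementation
  choice recorded in run manifests, not a source value).
* The two-phase switch has no printed formula; the $\lambda$-crossing root
  is used, with the fitness-scan cross-check.
* The quasi-static presets' per-curve mean rates are not printed; the
  `fig2a` preset defaults to $\{0.05, 0.1, 0.2\}$ purely for illustration.
* Configs are JSON (no YAML parser in the target environment); empirical
  rate lists travel as single-column CSV with header `f`.
* Continuous-distribution models with $n < 100$ warn that an explicit
  empirical rate list is the better representation of a small strain pool.

## Known limitations

Absolute fitness values depend on the $N_0$ convention (above). The
Legendre–Clebsch check is a numerical sign test, not a proof. Lognormal
trajectories are an order of magnitude slower than the closed-form kinds
because every $g(t)$ evaluation is a 128-node quadrature. The optimizer's
objective is not concave in the discretized control; multi-start L-BFGS-B
has always located the analytic optimum in the tested regimes, but global
optimality is certified only against the analytic candidate and random
schedules, not in general.
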