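---
title: "Methods: exhaustion-structured tumour-immune models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exhaustion-structured tumour-immune models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exhaustim)
```

## The model family

`exhaustim` implements three coupled descriptions of the same biology: a
tumour growing logistically towards its carrying capacity while cytotoxic
T-cells infiltrate, kill tumour cells, become progressively exhausted under
chronic antigen stimulation, and die.

**Compartment model.** The T-cell population is split into `n + 1` classes by
exhaustion level `j/n`. Three modelling assumptions shape the equations:

* *Recruited cells are fully active.* All influx enters `T_0`, at the
  dimensionless rate `sigma(N) = 1 + sigma_t * N / (1 + (N/N_t)^2)`. The
  biphasic form captures chemokine-driven recruitment by small tumours and
  the exclusion of T-cells by large ones; influx peaks at `N = N_t` with
  value `1 + sigma_t * N_t / 2` and decays back to the basal rate 1.
* *Exhaustion is antigen-driven and self-limiting.* Cells advance
  `j -> j + 1` at rate `(kappa0 + kappa1 * N) * n * (1 - j/n)`. The factor
  `n` makes the drift speed of the exhaustion level independent of how
  finely the spectrum is discretised; the factor `(1 - j/n)` encodes the
  reduced responsiveness of already-exhausted cells, and makes the terminal
  class absorbing (it loses cells only to death, at rate `gamma_t`).
* *Killing degrades linearly with exhaustion.* A class-`j` cell kills at
  `lam_t * (1 - j/n)`, so the tumour obeys
  `dN/dt = N(1 - N) - lam_t * N * sum_j (1 - j/n) T_j`.

**Reduced model.** The total `Theta` and mean exhaustion `mu` close exactly:
the weighted kill term equals `Theta * (1 - mu)`, so `(Theta, mu, N)` obey a
self-contained three-variable system. This is an algebraic identity of the
compartment equations, not a closure approximation, and the test suite
treats it as such: compartment moments must match the reduced trajectories
to a relative error of 1e-6 (solver error only) for `n` in {1, 10, 100}.
The compartment tumour equation is written with the weighted sum
`sum_j (1 - j/n) T_j` precisely so that this equivalence is exact.

**Continuum model.** Writing `s = j/n` and letting `n -> infinity` turns the
compartments into a transport equation with velocity
`v(s, t) = (kappa0 + kappa1 * N(t)) * (1 - s)` and decay `gamma_t`. With
`N(t)` supplied by the reduced model, the characteristics integrate in
closed form. The plane splits along the wavefront
`S(t) = 1 - exp(-K(t))`, `K(t) = integral of kappa0 + kappa1 * N(u)`:
ahead of the front the initial (tumour-free steady) profile is advected and
amplified; behind it the density is set by the boundary influx at the
infiltration time `t0(s, t)` obtained by inverting the clock `K`. Only the
leading-order velocity is used; the first-order correction terms in `1/n`
are out of scope, which is why the discrete and continuum solutions are
compared away from the front (see below).

## Parameters

Dimensional defaults (rates per day, cells in absolute counts): growth rate
`r = 0.18`, carrying capacity `K = 5e8`, kill rate `lam = 1.101e-7`, basal
influx `sigma0 = 1.3e4`, tumour-stimulated influx `sigma1 = 0.049`, influx-
maximising size `Nbar = 2e7`, basal exhaustion `k0 = 0.01`, tumour-enhanced
exhaustion `k1 = 5e-10`, T-cell death `gamma = 0.0412`, initial tumour
`N0hat = 1e7`. Nondimensionalisation scales time by `1/r`, tumour burden by
`K` and T-cell counts by `sigma0/r`, producing the groupings

```{r}
nondimensionalise(dimensional_parameters())
```

Internally all values are kept at full precision; printed values are
display-rounded to three significant figures (round-half-up), which is why
`sigma_t` displays as 1885 while the computed ratio is 1884.615...

The compartment count defaults to `n = 10`. Dimensionless parameter sets may
also be supplied directly — the analysis functions work purely in
dimensionless variables — in which case conversions to days (treatment
breakpoints, axis labels) fall back to the default `r = 0.18`.

The tunable parameters that matter most for the qualitative behaviour are
the kill rate `lam_t` and exhaustion rate `kappa1`; they are the axes of the
two-parameter region map because they are the quantities immunotherapies
plausibly move (CAR-T raises `lam_t`, checkpoint blockade lowers `kappa1`).

## Random parameter generation

`sample_parameters()` draws dimensional sets from the literature ranges used
to parameterise the model: `r` in [0.1, 0.5], `K` in [1e8, 1e10], `lam` in
[1e-8, 1e-4], `sigma1` in [0.001, 0.05], `k0` in [0.001, 0.01], `k1` in
[1e-11, 1e-8], `gamma` in [0.02, 0.05], `N0hat` in [1e7, 1e8]. Quantities
whose range spans at least two orders of magnitude (`K`, `lam`, `k1`) are
drawn log-uniformly so that small-magnitude regimes are represented;
narrower ranges are drawn uniformly. `sigma0` and `Nbar`, for which single
literature values are used, are held fixed. These draws emulate plausible
between-patient variability in the published ranges, nothing more: passing
the property suites under these draws says the *mathematics* (root counts,
parity, eigenvalues) is implemented correctly across the ranges, not that
the model is validated against any real cohort.

## Steady states, stability, bifurcations

Nontrivial steady states satisfy `1 - N = f(N)` with
`f(N) = lam_t * sigma(N) / (gamma_t + kappa0 + kappa1 * N)`. Clearing the
strictly positive denominators gives a quartic whose real roots in (0, 1)
are exactly the nontrivial states, so root-finding is done once, globally,
by `polyroot` (companion-matrix eigenvalues) with the following numerical
policy: keep roots with imaginary part below 1e-9 and real part in
(1e-12, 1 - 1e-12), deduplicate within 1e-8, then polish each by bisection
on `1 - N - f(N)` where a sign change brackets it (near-double roots at
folds are kept unpolished). Roots at or above the carrying capacity are
discarded as unphysical. The count is the tumour-free state plus these
roots, and is at most five; the parity of the nontrivial count follows the
sign of `f(0) - 1` (odd when `f(0) < 1`, even otherwise).

Stability comes from the closed-form spectrum: `-gamma_t` always, plus the
roots of `alpha^2 + (gamma_t + k(N*) + N*) alpha - N* g(N*)`, so the sign of
`g(N*) = -gamma_t - k(N*) + (1 - N*) k'(N*) - lam_t * sigma'(N*)` decides
stability and `g = 0` locates folds. The test suite cross-checks this
spectrum against central-difference Jacobians of the right-hand side at a
hundred randomly sampled steady states (tolerance 1e-6).

Because the steady-state relation is single-valued in `N*`, one-parameter
branches are computed by explicit parametrisation —
`lam_t(N*) = (1 - N*)(gamma_t + kappa0 + kappa1 N*) / sigma(N*)` and the
analogous `kappa1(N*)` — rather than pseudo-arclength continuation, which
would add machinery without adding robustness here. Folds are sign changes
of the parametrisation's derivative along a 4001-point grid, refined by
bisection to an `N*` width of 1e-10.

**Outcome labels.** The tumour-free state is `elimination`; among stable
positive roots the smaller branch is `equilibrium` and the larger `escape`;
unstable interior roots are `intermediate`. When only one stable positive
root exists its branch identity is decided by (in order): an unstable root
below it (then it is the escape branch), an unstable root above it (the
equilibrium branch), or its position relative to the stationary points of
the `lam_t(N*)` parametrisation, which depend only on `kappa1` and the
influx parameters. If the parametrisation is monotone the two branches are
genuinely connected and the label falls back to a midpoint tie-break at
`N* = 0.5`; with the default influx parameters this fallback is never
reached. The two-parameter region map keys cells by the triple (state
count, stable count, stable-outcome set); with the default influx
parameters this partitions the `(lam_t, kappa1)` plane into exactly five
regions.

**Tristability.** The window in which all three outcomes are simultaneously
stable exists only for weak, broad influx (around
`sigma_t = 3.3, N_t = 0.45`) and is extremely narrow in `lam_t` (width of
order 1e-4 near 0.29). A plain log-spaced sweep can step over it, so
`tristability_window()` augments the sweep grid with geometric midpoints
between consecutive branch breakpoints (folds and the transcritical point),
which guarantees one evaluation inside every inter-breakpoint interval
while leaving the reported quantity — the maximum coexisting state count —
unchanged.

## Simulation and outcome classification

Both ODE systems are integrated with deSolve's adaptive Runge-Kutta 4(5)
(`ode45`), relative tolerance 1e-8 and absolute tolerance 1e-10 — tight
enough that the moment-closure equivalence tests at 1e-6 measure model
identity rather than solver noise. State invariants (positive `Theta`,
`mu` in [0, 1], non-negative compartments and `N`) are asserted at output
points with a 1e-9 slack and never silently clipped.

A trajectory is classified by its endpoint: `elimination` below a burden of
1e-4 (about 5e4 cells at the default carrying capacity — the model has no
intrinsic extinction threshold, so one must be chosen; this one sits far
below every nontrivial steady state encountered in the default regimes),
otherwise the outcome of the nearest stable steady state in `N`. If the
right-hand side's sup-norm at the endpoint exceeds 1e-6 the integration is
continued, up to ten times the original horizon, before `undecided` is
returned.

**Treatment.** A course of therapy is a trapezoid in time applied to
`kappa1`: baseline until `t_on`, linear ramp down over `ramp` days to
`kappa1 - delta_kappa`, a plateau, and a symmetric ramp back (defaults
100/25/50/25 days, `delta_kappa = 1.2`). Breakpoints are specified in days
because that is how treatment courses are prescribed; the integrator runs
in dimensionless time and converts internally via the growth rate. The
treatment scenarios are initialised exactly at the escape steady state
(distribution included, via the analytic steady distribution), the cleanest
realisation of "a patient presenting with a large tumour burden"; no
additional perturbation is applied.

## Continuum solution: numerical choices

The exhaustion clock `K(t)` and the auxiliary integral of `N` are
accumulated by the trapezoidal rule on a 1e4-point reduced trajectory,
giving inversion errors comfortably below 1e-8; `t0(s, t)` is found by
monotone linear interpolation of the clock, and `N(t0)` by linear
interpolation of the stored trajectory. Evaluation is capped at
`s = 1 - 1e-3` because the recruited-cell branch carries a `1/(1 - s)`
singularity at the fully exhausted end, where the leading-order continuum
approximation ceases to be valid. The front discontinuity is represented,
not smoothed.

When the compartment and continuum solutions are compared
(`compare_with_discrete()`), compartment masses are rescaled by `n` (the
density identification `T(s, t) ~ n T_j`), the window is restricted to
`s <= 0.9`, and a band of half-width `2/n` around `S(t)` is excluded: the
discrete front is smeared over a width of order `n^{-1/2}`, so the
near-front mismatch is a property of the discretisation, not an
implementation error. The L1 discrepancy then falls monotonically over
`n = 10, 100, 1000`. With `kappa1 = 0` the characteristics construction is
cross-validated against the fully explicit two-branch closed form to 1e-10.

One identity is deliberately verified rather than re-derived: the
resident-region density's amplification factor
`exp((gamma_t * kappa1 / kappa0) * integral of N)` is implemented as stated
and confirmed numerically by a finite-difference residual of the transport
equation on smooth interior points (tolerance 1e-3, grid-limited).

## Problem sizes

The default test and acceptance workloads were chosen as the smallest sizes
at which each property is cleanly resolved: 250-day horizons for the
qualitative regimes; `n` in {1, 10, 100} for closure tests and up to 1000
for the continuum comparison; 4001-point branch grids; a 200x200 region
map; 1e4-point kill-rate sweeps; 1e4 random parameter sets for the census
bound; 100 random steady states for the eigenvalue cross-check.

## Known limitations

* The closed-form variance of the exhaustion distribution is not
  implemented; variances are computed numerically from distributions.
* The continuum model is leading-order only: no `1/n` correction terms, so
  the front region and `s -> 1` are approximated poorly by construction.
* No spatial structure, stochasticity, cytokine dynamics, additional immune
  cell types, or exhaustion-dependent proliferation/influx; no fitting to
  patient data. The parameter values are representative, intended for
  qualitative insight.
* Average transit time across the full exhaustion spectrum in the
  compartment model grows like the harmonic number `H_n / k` — the discrete
  shadow of the continuum fact that `s = 1` is only reached asymptotically.
  What the `n`-scaling of the rates guarantees (and what the tests assert)
  is that the *drift of the mean exhaustion level* of a cohort,
  `1 - exp(-k t)`, is independent of `n`.
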