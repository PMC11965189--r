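# exhaustim

Tumour–immune dynamics with exhaustion-structured cytotoxic T-cells.

## The problem and who this is for

Chronic antigen stimulation inside the tumour microenvironment drives
cytotoxic T-cells into progressively "exhausted" states in which they kill
tumour cells less effectively. `exhaustim` is for mathematical oncologists and
systems biologists who want a tested, scriptable implementation of a family of
structured tumour–immune models built around that process:

1. **Compartment ODE model.** T-cells are split into `n + 1` subpopulations
   `T_0, ..., T_n` by exhaustion level `j/n`. Fully active cells (`j = 0`)
   infiltrate at the biphasic rate
   `σ(N) = 1 + σ̃N / (1 + (N/Ñ)²)`, drift towards exhaustion at rate
   `k(N)·n·(1 − j/n)` with `k(N) = κ₀ + κ₁N`, and all die at rate `γ̃`. The
   tumour burden `N` (as a fraction of carrying capacity) obeys
   `dN/dt = N(1 − N) − λ̃ N Σⱼ (1 − j/n) Tⱼ`.
2. **Reduced ODE model.** The total `Θ = Σ Tⱼ` and mean exhaustion level
   `μ = Σ (j/n) Tⱼ / Θ` satisfy a *closed* three-variable system — the moment
   reduction is exact, not an approximation — with
   `dN/dt = N(1 − N) − λ̃ N Θ(1 − μ)`.
3. **Continuum (PDE) model.** In the limit `n → ∞` the compartments become a
   transport equation `∂T/∂t + ∂/∂s[(κ₀ + κ₁N(t))(1 − s)T] = −γ̃T` on the
   exhaustion spectrum `s ∈ [0, 1]`, solved here analytically by the method of
   characteristics, with an exhaustion wavefront
   `S(t) = 1 − exp(−∫₀ᵗ (κ₀ + κ₁N) du)` separating resident from recruited
   T-cells.

On top of the simulators the package provides full steady-state analysis
(the nontrivial steady states are the roots of a quartic in `(0, 1)`), linear
stability via closed-form eigenvalues, fold/transcritical bifurcation
tracking, two-parameter region maps over the kill rate `λ̃` and exhaustion
rate `κ₁`, detection of the tristable regime in which elimination,
equilibrium and escape are simultaneously stable, and a trapezoidal
treatment schedule that transiently lowers `κ₁` (an immune-checkpoint-
inhibitor caricature).

## Worked example

```r
library(exhaustim)

m <- exhaustion_model()        # literature parameter set, n = 10
summary(m)
```

```
Steady states of the reduced tumour-immune model
  N_star Theta_star mu_star   p_star stable      outcome      eig1            eig2            eig3
 0.00000     4.3668 0.19536 -3.11871  FALSE  elimination -0.229+0i -0.2846+0.0000i  0.8447+0.0000i
 0.00294    28.4374 0.20675 -2.83670   TRUE  equilibrium -0.229+0i -0.1458+0.4653i -0.1458-0.4653i
 0.29397    48.3543 0.66966  0.50669  FALSE intermediate -0.229+0i  0.3767+0.0000i -1.3640+0.0000i
 0.86745    19.5174 0.84634  0.81845   TRUE       escape -0.229+0i -0.5390+0.0000i -1.8190+0.0000i
f(0) = 0.1553; transcritical threshold lam_tr = 0.2846 (lam_t below: tumour-free state unstable)
```

The default parameters are *bistable*: a stable coexistence equilibrium at
`N* ≈ 0.0029` (about 1.5 million tumour cells at the default carrying
capacity of 5×10⁸) with a large, mostly active T-cell population
(`Θ* ≈ 28.4`, `μ* ≈ 0.21`, complex eigenvalues — a damped-oscillation
focus), and a stable escape state at `N* ≈ 0.87` with a smaller, chronically
exhausted T-cell population (`μ* ≈ 0.85`, skew `p* > 0`: the steady
exhaustion distribution is increasing). The tumour-free state is unstable
because `λ̃ = 0.0442` lies below the transcritical threshold
`λ_tr = γ̃ + κ₀ = 0.2846`.

```r
traj <- simulate(m, t_end_days = 250)   # reduced model, RK45
classify_outcome(traj)
#> [1] "equilibrium"
tail(as.data.frame(traj), 1)
#>      time    Theta        mu           N
#> 2001   45 28.49747 0.2063701 0.002945225
```

Starting from a small tumour (`N₀ = 0.02`), predator–prey-like damped
oscillations settle onto the equilibrium branch. Raising the kill rate to
`λ̃ = 0.29` (`> λ_tr`) yields `"elimination"`; raising the exhaustion rate to
`κ₁ = 80` yields `"escape"`. `simulate(m, which = "discrete")` runs the
compartment model, whose moments reproduce the reduced trajectory to solver
precision, and `run_scenario("treatment_responsive")` /
`run_scenario("treatment_refractory")` contrast a durable response with a
relapse under the same treatment course.

A thin command-line front end over the same functions is installed at
`inst/cli/texh.R` (`Rscript texh.R steady-states --params file.yaml --out
steadies.json`, etc.).

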