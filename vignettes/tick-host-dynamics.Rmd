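---
title: "Methods: the coupled algebraic-delay tick-host model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coupled algebraic-delay tick-host model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tickdde)
```

## The model and its assumptions

The package tracks one tick development stage (nymphs) through the
tick-host interface with two state variables: engorged nymphs on the
ground, $E(t)$, and feeding nymphs on hosts, $F(t)$. The standing
assumptions are:

* the host population is static, so the per-host feeding load is
  proportional to $F$, and the attachment rate of questing nymphs is a
  $C^1$ nonnegative function $\rho(F)$ of the total feeding load;
* grooming-driven drop-off acts per feeding tick at a $C^1$ nonnegative
  rate $\nu(F)$;
* engorged nymphs leave their stage at rate $\delta$ and return as
  questing nymphs after the development delay $\tau$, with composite gain
  $\eta = \eta_2\sigma\eta_1$ (survival to egg-laying adult, egg
  production, survival from egg to questing nymph);
* a blood meal takes $T$ days, so the full life cycle spans $\tau + T$.

Structuring feeding ticks by time-since-attachment $a\in[0,T]$ gives a
transport equation with grooming mortality; integrating along
characteristics turns the stage into an algebraic constraint
$$F(t) = \int_0^T e^{-\int_{-a}^{0}\nu(F(t+\xi))d\xi}\,
  \rho(F(t-a))\,\eta E(t-\tau-a)\,da,$$
coupled to
$$E'(t) = -\delta E(t) +
  e^{-\int_{t-T}^{t}\nu(F)}\rho(F(t-T))\,\eta E(t-\tau-T).$$
Differentiating the constraint yields an equivalent pair of delay
equations *provided the initial data satisfy the constraint at* $t=0$ (the
matching condition); the constraint is then conserved along the solution,
and nonnegative matched histories produce nonnegative solutions.

## Behaviour families and parameters

| family | $\rho(F)$ | $\nu(F)$ | parameters (units) |
|---|---|---|---|
| `constant` | $p$ | $\mu_0$ | $p$ (1/day), $\mu_0$ (1/day) |
| `monotone` | $p e^{-F/c}$ | $\mu F + \mu_0$ | $c$ (ticks), $\mu$ (1/(tick day)) |
| `ricker_linear` | $pFe^{-F/c}$ | $\mu F + \mu_0$ | $p$ (1/(tick day)), $c$ (ticks) |
| `holling3_reactive` | $rF/(1+F^2/j^2)$ | $k\rho(F)$ | $r$ (1/(tick day)), $j$ (ticks), $k$ (days) |

The Ricker family encodes cooperative-then-self-limiting attachment
(maximal at the capacity $F=c$); Holling type III encodes improving search
for suitable skin (maximal value $rj/2$ at $F=j$); $\nu = k\rho$ models
grooming triggered by biting itself. A scenario object carries each
function *with its analytic derivative*, so stability calculations never
differentiate numerically at an equilibrium.

The two presets fix the study conditions used throughout the tests:
`bi` ($\eta_1=0.15$, $\eta_2=0.3$, $\sigma=1000$, $\tau=700$, $T=7$,
$p=0.002$, $\delta=0.033$, $\mu_0=0.4$, $\mu=0.0014$, $c=100$;
Ricker/linear) and `quadri` ($\eta_1=0.05$, $\eta_2=0.1$, $\sigma=300$,
$\tau=700$, $T=7$, $\delta=0.2$, $k=2/7$, $r=0.02$, $j=120$; Holling
III/reactive).

## Equilibrium structure and solver numerics

Nontrivial equilibria solve
$\nu(F^*) = T^{-1}\log(\eta\rho(F^*)/\delta)$ with
$E^* = F^*\nu(F^*)/(\eta\rho(F^*)-\delta)$. For the Ricker family this
reduces to $x e^{-(1/c+\mu T)x} = \delta(\eta p)^{-1}e^{\mu_0 T}$; for the
reactive family to $\rho e^{-kT\rho} = \delta/\eta$ followed by the
closed-form quadratic inversion of the Holling curve. Both reduced
equations are unimodal, so the solvers bracket each monotone side of the
analytic maximiser and run `uniroot` with Newton polish. Numerical
choices:

* absolute tolerance $10^{-12}$ on the reduced-equation residual,
  relative tolerance $10^{-10}$ on $F$ — published 4-decimal reference
  values need only $10^{-5}$, leaving a wide margin;
* tangency (fold) detection uses a relative gap of $10^{-9}$ between the
  right-hand side and the unimodal maximum, because exact equality is
  measure-zero in floating point; the equality case returns a single
  equilibrium flagged `critical` rather than two coincident rows;
* upper brackets expand geometrically from
  $100\max(c, j, (1/c+\mu T)^{-1})$ until the decaying side falls below
  the target.

Every returned table carries the equilibrium-equation residual so a
downstream user can see the solution quality directly.

## Stability classification

Linearising about a positive equilibrium gives a $2\times2$ spectral
problem whose determinant mixes exponentials and distributed-delay
kernels; locating its rightmost zero in general is out of reach, so the
classifiers exploit the short feeding duration ($T = 7$ d against a
$\tau + T = 707$ d cycle) and expand in $T$:

* **Ricker/linear grooming.** The leading eigenvalue coefficient
  $\lambda_0$ solves $-(F_0/c)\lambda_0 + \delta e^{-\lambda_0\tau} =
  (F_0/c)\delta$; its sign is positive exactly when $F_0 < c$. Hence the
  lower branch is unstable and the upper branch stable — bi-stability
  together with the (always stable, since $\rho(0)=0$) tick-free state.
* **Holling III/reactive grooming.** With strong per-attachment grooming
  the natural scaling holds $k_0 = kT$ fixed; the package reads the
  preset's grooming coefficient this way ($k_0 = kT$, and the first-order
  correction $k_1 = 0$, a choice the expansion leaves free). The leading
  term reduces to a scalar delay equation whose effective feedback
  constant $A$ classifies each branch: stable iff $A > 0$, under the
  hypotheses $\eta E_0\tilde\rho_0 e^{-k_0\rho_0} < 1$ and $\delta > A$.
  Both hypotheses are checked and *gate* the verdict: when either fails
  the branch is reported `undetermined`, never guessed.

Sign calls within $10^{-9}$ of zero are reported `undetermined` to avoid
asserting stability at numerical boundaries. A warning is emitted whenever
$T/(\tau+T) > 0.1$, since the verdicts are first-order in $T$. Beyond the
perturbation formulas, the characteristic determinant is exposed directly
(`char_entries`, `char_det`) with a real-axis sign-change scan and an
argument-principle contour count as diagnostics; full spectral
certification is intentionally out of scope.

## The integrator

The differentiated form is integrated with the identity that, on the
constraint manifold, the trailing distributed-delay term equals
$\nu(F(t))F(t)$ — this avoids solving the integral equation implicitly at
every step. The running grooming exposure
$S(t)=\int_{t-T}^t\nu(F)$ is carried as a third state with
$S' = \nu(F(t)) - \nu(F(t-T))$, re-synchronised by full quadrature every
$10^4$ steps to bound drift.

Stepping is classical RK4 on a fixed grid with $h$ dividing both $T$ and
$\tau$ (default $h = T/70 = 0.1$ d, making $T/h = 70$ and $\tau/h = 7000$
exact). Delayed values at half-steps are interpolated by *cubic Hermite*
from stored values and derivatives; linear interpolation would cap the
scheme at second order, while the Hermite interpolant keeps the observed
fourth-order convergence of the constraint residual (measured ratio 16.0
per halving of $h$ on both presets). One subtlety: the solution's first
derivative generally jumps where the history meets the solution at $t=0$,
so interpolation on the grid interval just left of that node uses the
history's one-sided derivative.

The algebraic equation is *monitored*, not enforced: at a configurable
cadence (default every 7 days) the integral right-hand side is recomputed
from stored history — inner survival integral by Hermite-corrected
trapezoid, outer integral by composite Simpson — and the relative residual
$|F - F_{\mathrm{alg}}|/\max(F,1)$ reported. With a matched history it
stays near $10^{-8}$ at $h=0.1$ over twenty life cycles.

Runs stop early when the state has stayed within relative distance
$10^{-4}$ of a supplied equilibrium for one full life cycle (convergence),
or past $10^{10}$ (divergence); otherwise they run to the horizon, default
$50(\tau+T)\approx 35{,}350$ d, because transients span dozens of
generations when delays run to hundreds of days.

## History construction

Initial data live on $[-\tau-T, 0]$. `make_history` builds constant or
function-valued histories and solves the matching condition in either
direction: given $E$, the constant feeding level is the fixed point of the
matching integral (damped iteration, relative tolerance $10^{-12}$, hard
error after $10^4$ iterations); given a prescribed feeding load $F_0$, the
constant engorged level is solved in closed form,
$E_0 = F_0\,\nu(F_0)/\big(\eta\rho(F_0)(1-e^{-\nu(F_0)T})\big)$. The
second form is how "initial feeding ticks $= X$" experiments are set up:
it keeps the initial load exactly $X$ while satisfying the matching
condition, and reproduces $E^*$ exactly when $X$ is an equilibrium load —
so equilibria remain fixed points of the discrete flow. Published basin
experiments for the bi-stable configuration give bare number pairs whose
$(E,F)$ ordering is ambiguous; the report runner exposes both orderings
rather than guessing.

## What the presets emulate — and what passing tests do not show

The presets are point estimates of a single-stage, single-host-class
interface with time-invariant rates. They emulate realistic magnitudes
(year-scale development delays, week-scale feeding, per-day rates) and the
qualitative behaviour combinations of interest. They do not emulate
seasonality or temperature dependence of rates, host population dynamics,
stage interactions, or demographic stochasticity — so green tests say the
*mechanism* (multi-stability from behaviour coupling) is computed
correctly, not that field populations sit at these equilibria. The
critical-case experiment uses a perturbed engorged history
$E(s) = 10(1 + 0.5\sin(s/100))$: a 50%-amplitude, 100-day-scale
fluctuation standing in for seasonal variability.

## Numerical limits worth knowing

* **Critical-case convergence is slow at preset scale.** At
  $R_0 = 1$ the engorged equation reduces to
  $E' = \delta(E(t-\tau-T) - E(t))$, whose nonzero characteristic roots
  for $\delta = 0.033$, $\tau+T = 707$ have real part
  $\approx -4.4\times10^{-5}$/day: a perturbation halves only every
  $\sim 16{,}000$ days. The simulator tests confirm the limit value (via
  the conservation law $E(t) + \delta\int_{t-\tau-T}^{t}E$) and the decay
  *rate* against the characteristic root; but after 50 life cycles a
  50%-amplitude history is still $\sim\!10\%$ from its limit, so
  tight-tolerance convergence checks at that horizon fail for structural,
  not numerical, reasons. The acceptance suite keeps that strict check
  as-is and it fails honestly.
* **Published bi-stable reference values.** The reference equilibrium
  pairs and the fold location quoted for the Ricker configuration are not
  simultaneous roots of the reduced equilibrium equation under the quoted
  parameters (the two $F$ values imply different right-hand sides).
  Reports therefore print computed and reference values side by side with
  the relative deviation; the quadri-stability references agree with
  computation to $<0.1\%$ once their 4-decimal rounding of the
  attachment-rate roots is accounted for.
* **Problem sizes.** Tests run at $h = T/70$ with horizons of 20 life
  cycles for conservation checks, 50 for basin and limit runs, and
  $10^3$-draw randomized oracles for the closed forms — sizes chosen so
  the whole suite exercises every code path at the presets' own scales.

## Known limitations

Hopf bifurcation detection, continuation of periodic orbits, and global
dynamics are out of scope (the perturbation verdicts are first-order local
statements). The integrator is explicit and fixed-step: appropriate here
because the behaviour rates are mild, but not for stiff extensions. The
equilibrium solvers cover the four named families, not arbitrary
user-supplied $(\rho,\nu)$ pairs.
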