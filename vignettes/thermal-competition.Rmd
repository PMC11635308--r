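---
title: "Methods: temperature-dependent competition with skewed thermal performance curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature-dependent competition with skewed thermal performance curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocompete)
```

This vignette is the package's account of its model, its numerical choices,
and the points where the design was genuinely open. Nothing here reports an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The model

Each species carries a thermal performance curve (TPC) for its intrinsic
growth rate and competes through the shared-sum Lotka–Volterra system

$$\frac{dN_i}{dt} = r_i(T)\, N_i \left(1 - \frac{\sum_j N_j}{K_i}\right),$$

i.e. every species experiences the *total* community density against its own
carrying capacity — all pairwise competition coefficients equal 1. This is
deliberately the simplest structure in which temperature can reorder
competitive outcomes: temperature enters only through $r_i(T)$; encounter
rates, consumption, movement and other temperature-dependent rates are out
of scope.

### The curve form

The growth-rate curve must be unimodal, anchored at zero at a cold limit
$T_{min}$ and a hot critical temperature $T_{max}$, peak at $T_{opt}$, and
be skewable so that the decline above the optimum can be much steeper than
the rise below it. The default is the beta (Yan–Hunt) form,

$$r(T) = r_{peak}\,
  \frac{T_{max}-T}{T_{max}-T_{opt}}
  \left(\frac{T-T_{min}}{T_{opt}-T_{min}}\right)^{(T_{opt}-T_{min})/(T_{max}-T_{opt})},$$

chosen because it satisfies every qualitative requirement with *no* shape
parameters beyond the three cardinal temperatures: its maximum is exactly
$r_{peak}$ at exactly $T_{opt}$, its zeros are exact, and skewness is
controlled purely by the spacing ratio

$$\mathrm{skew} = \frac{T_{max}-T_{opt}}{T_{opt}-T_{min}},$$

with values below 1 giving the characteristic right-skewed shape. Because
skewness is a pure spacing property, "varying skewness" is a
one-dimensional, monotone operation (move $T_{max}$ around a fixed
$T_{opt}$), which keeps the robustness ensemble interpretable. A form
registry (`register_tpc_form()`) allows alternates — a sharpened `beta2`
ships with the package — for sensitivity checks; all registered forms must
peak at $T_{opt}$.

### Behaviour outside the thermal window

Below $T_{min}$ the rate is clamped at 0: cold temperatures shut growth down
but are not treated as lethal. Above $T_{max}$ the default extends the curve
linearly *negative* with slope `death_slope` (default 0.1 per °C per unit
time): organisms past their critical maximum pay maintenance and mortality
costs, they do not merely stop growing. `death_slope = 0` switches this off
and clamps the hot side at 0 instead; the switch exists because the choice
is a genuine modelling decision, and the dominance structure below
$T_{max}$ does not depend on it.

### Default community

The default three-species community shares $T_{min} = 0$ °C and brackets a
37 °C environmental reference ceiling (the long-term mean maximum ocean
temperature motivating the experiment):

| species | $T_{opt}$ | $T_{max}$ | skew |
|---------|-----------|-----------|------|
| S3 | 32 | 37 | 0.156 |
| S1 | 37 | 41 | 0.108 |
| S2 | 42 | 46 | 0.095 |

All peaks are normalized to 1 per unit time, so the ranking of curves at any
temperature reflects spacing and skewness, not raw peak height — S2 is the
most skewed, S3 the least, matching the usual pattern that hotter-adapted
curves are more asymmetric. Time units are arbitrary; `r_peak = 1` sets the
clock.

Carrying capacities are equal ($K_i = 1$) and initial densities equal at 1 %
of capacity. Both are deliberate. Under the shared-sum equations, unequal
capacities hand victory to the largest-$K$ species at *every* temperature
(the bracket of the largest-$K$ species is the last to reach zero), which
would erase the temperature dependence the model exists to study; equal
capacities instead make the outcome a clean function of the rates. Equal
initial densities put all species on an equal footing so that steady-state
ranking equals growth-rate ranking (next section).

## The composition law, and what "steady state" means

For equal capacities the system has an exact first integral: dividing the
per-capita equations,

$$\frac{d\,\ln N_i}{d\,\ln N_j} = \frac{r_i}{r_j}$$

is constant in time, so the steady state satisfies
$N_i^* = N_i(0)\, g^{\,r_i}$ for a single community-wide scalar $g$ fixed by
$\sum_i N_i^* = K$. Three consequences shape the whole package:

1. **Ranking.** With equal initial densities, steady-state density ranking
   equals growth-rate ranking — the dominant species at any temperature is
   the fastest grower there. The sweep's dominance structure is therefore
   an exact, testable consequence of the curve geometry.
2. **Persistence.** Since $g > 1$ (the community grows from 1 % of
   capacity), any species with $r_i > 0$ ends *above* its initial 1 %
   share. The persistence of the intermediate-optimum species across its
   entire growth range is a theorem under these conditions, not a numerical
   accident.
3. **Remnants, not extinctions.** The law holds for negative exponents too.
   A species pushed past its $T_{max}$ (negative $r_i$) while a competitor
   still grows does **not** go extinct: once the growing species saturate
   the shared capacity, the bracket $(1 - \sum N/K)$ collapses to zero and
   the decliner freezes at the positive remnant $N_i(0)\,g^{\,r_i}$,
   because $\int_0^\infty (1 - \sum N/K)\,dt$ is finite. In the default
   community at 42 °C, S3's remnant is $\approx 10^{-3}$ — visually zero in
   a figure, but not zero. Exact extinction above $T_{max}$ occurs only in
   isolation or when *every* species is past its critical maximum. This is
   a property of the shared-sum equations themselves; the acceptance suite
   asserts the strict per-species extinction reading and documents its
   failure rather than papering over it.

"Steady state" is operationalised by a derivative criterion:
integration (stiff-capable `deSolve::lsodar`, rtol $10^{-8}$, atol
$10^{-12}$) stops when $\max_i |dN_i/dt| < 10^{-9}$ (root function), or at a
horizon of $10^4$ time units with the convergence flag cleared. A
state-difference criterion would be wrong here: the equal-$K$ system
converges to a neutrally stable manifold ($\sum N = K$, any composition),
so only the derivative reliably detects arrival.

At termination, densities below $10^{-9}\bar K$ are reported as exactly 0.
One subtlety: pure exponential decay halts at density
$\approx \mathrm{deriv\_tol}/|r|$, which can sit just *above* that
threshold. A converged species whose per-capita rate
$r_i(1 - \sum N/K_i)$ is still strictly negative (below
$-10^3 \times$ the derivative tolerance, a cutoff sitting many orders of
magnitude between the two regimes) is decaying exponentially with no
mechanism of rescue, so its exact steady state is 0 and it is reported as
extinct; species frozen on the capacity manifold (bracket $\approx 0$) are
untouched by this rule and keep their remnant.

## The temperature sweep

The "continuous" 25–45 °C range is discretised at 0.1 °C (201 points),
finer than any dominance feature of interest; the step is configurable and
a grid-refinement test checks that halving it moves interval boundaries by
at most one coarse step. Every grid point is an independent cold start from
the initial densities — the sweep maps equilibrium outcomes, not a
time-varying climate with thermal history.

Dominance at a grid point is the strictly largest density; if the top two
densities are within a relative `tie_tol` ($10^{-6}$) the point is reported
as a tie, never silently broken, and if all species are extinct it is
"none". `dominance_intervals()` run-length encodes the grid into maximal
single-species intervals; ties and all-extinct points break runs.

## The robustness ensemble

The ensemble re-runs the sweep under seeded perturbations of the default
community, one factor at a time (uniform draws over declared ranges,
`withr::with_seed` for bit-for-bit reproducibility):

- **skewness** — one skew ratio drawn from [0.05, 0.8] applied to all
  species ($T_{max}$ moves, $T_{opt}$ fixed);
- **spacing** — one gap drawn from [2, 8] °C between adjacent optima,
  centred on 37 °C, each species keeping its own hot-side offset (a 5 °C
  draw reproduces the default optima 32/37/42);
- **normalization** — *independent* per-species skews and raw peak rates
  ($r_{peak} \sim U(0.5, 1.5)$), with the normalize-to-common-peak switch
  alternating on/off across draws. Peak draws are needed to make the
  switch a real contrast: under the beta form the peak *is* $r_{peak}$, so
  skew variation alone cannot de-normalize anything;
- **pairwise** — every two-species subset of the base community, unchanged.

Two flags are recorded per scenario: monotone hand-over (the dominant
species' $T_{opt}$ never decreases as the grid warms) and intermediate
persistence (every middle-optimum species holds > 1 % of total density
wherever its rate is positive). In the default regime both hold in 100 % of
skewness, spacing and pairwise scenarios — a consequence of the ranking
property plus the fact that these variations keep each pair of curves
crossing at most once inside the grid. The normalization axis can
legitimately break monotonicity: independent skews can give a
lower-optimum species a *higher* $T_{max}$ than a hotter-optimum rival, the
two curves then cross twice in-grid, and dominance flips back at the hot
edge. The ensemble reports this rather than asserting it away; it is the
model's own version of "consistent except under extreme variation".

### The degenerate-spacing probe

Near-identical competitors should produce uninformative (tie-flagged)
outcomes. The onset scale is quadratic, not linear: for optima separated by
$\delta$, all curves near the shared peak differ by
$\tfrac12 |r''(T_{opt})|\,\delta^2$, so the top-two relative density gap is
$\approx \ln(g)\,\tfrac12 |r''|\,\delta^2$, and ties at
`tie_tol` $= 10^{-6}$ require $\delta \lesssim 3\times10^{-3}$ °C. A
uniform draw over (0, 0.1] °C would almost never reach that scale, so the
degenerate probe draws spacing *log-uniformly* over $[10^{-4}, 0.1]$ °C —
the natural prior for a scale parameter probed across decades
(`spacing_scale = "log"`). About half the draws then land below onset, and
the probe flags ties with near certainty at any seed.

## What the generator does and does not emulate

The scenario generator emulates *known interspecific variation in thermal
performance curves*: staggered optima, varying asymmetry, varying peak
height, smaller communities. It does not emulate measurement noise, within-
species plasticity or acclimation, temperature-dependent interaction
coefficients, stochastic or spatially structured environments, or evolution
of the curves themselves (phenotypes are fixed). Passing tests therefore
show that the dominance pattern is a robust property of this model class —
not that real communities obey it.

## Problem sizes and runtime

The suite and the acceptance script run the full default grid (201 points),
a 23-scenario robustness battery plus a 10-scenario degenerate probe at the
same resolution, 100 random communities for the conservation-law check, and
coarser grids (0.25–1 °C) for unit tests: a few minutes on one CPU. These
sizes were chosen so a complete from-scratch reproduction is an interactive
operation.

## Known limitations

- Equal carrying capacities are load-bearing (see above); the package
  exposes unequal $K$ but the dominance-equals-rate interpretation, the
  persistence theorem and the composition-law oracle all assume equal $K$.
- The shared-sum structure cannot produce stable multi-species coexistence
  at a *point* equilibrium — coexistence lives on the neutral manifold, and
  relative outcomes depend on initial densities (kept equal by default).
- Near the hot edge of the grid, all rates can be tiny and convergence to
  the derivative tolerance slow; points that hit the $10^4$ horizon are
  flagged unconverged rather than silently accepted.
- The linear death extension above $T_{max}$ is a minimal stand-in for
  heat mortality; its slope rescales how fast hot-side remnants shrink but
  not who dominates below $T_{max}$.
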