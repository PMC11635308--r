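# thermocompete

Temperature-dependent Lotka–Volterra competition with skewed thermal
performance curves.

## The scientific problem

Most organisms grow fastest at temperatures below ~40 °C, with a thermal
performance curve (TPC) that rises gradually from a cold limit, peaks at an
optimum T_opt, and collapses quickly toward an upper critical temperature
T_max. A long-standing question in thermal ecology is why growth optima
cluster so tightly under this ceiling. One candidate mechanism is purely
competitive: in an environment whose temperature rarely exceeds some ceiling
(~37 °C for the oceans over geological time), species whose optima sit at or
just below that ceiling systematically outgrow — and therefore outcompete —
both colder- and hotter-adapted rivals.

`thermocompete` is a simulation toolkit for exploring that mechanism. It is
aimed at theoretical ecologists who want a tested, reproducible pipeline for
competition-versus-temperature experiments rather than one-off scripts.

## The model

Each species *i* has a right-skewed TPC for its intrinsic growth rate. The
default functional form is the beta (Yan–Hunt) curve, parameterised entirely
by three cardinal temperatures and a peak rate:

```
r_i(T) = r_peak * ((T_max - T) / (T_max - T_opt)) *
         ((T - T_min) / (T_opt - T_min)) ^ ((T_opt - T_min) / (T_max - T_opt))
```

for `T_min < T < T_max`, with `r_i = 0` at and below `T_min`, `r_i = 0` at
`T_max`, and `r_i = -death_slope * (T - T_max)` above `T_max` (net mortality
past the critical maximum). Skewness is the spacing ratio
`(T_max - T_opt) / (T_opt - T_min)`; values below 1 give the
characteristic steep decline above the optimum.

At a fixed environmental temperature *T*, densities follow shared-sum
Lotka–Volterra competition (all pairwise competition coefficients equal 1):

```
dN_i/dt = r_i(T) * N_i * (1 - (Σ_j N_j) / K_i)
```

The system is integrated to steady state (`deSolve::lsodar` with a
root-function stop on `max_i |dN_i/dt|`), swept over a continuous
temperature range (25–45 °C at 0.1 °C by default, every point an independent
cold start), and summarised by which species dominates where. A seeded
robustness ensemble perturbs curve skewness, optimum spacing, peak
normalization, and pairwise species subsets to test how stable the dominance
pattern is.

For equal carrying capacities the model admits an exact conservation law —
`ln(N_i*/N_i(0)) / r_i` is the same for every species — which the test suite
uses as an independent oracle for multi-species outcomes.

## Worked example

```r
library(thermocompete)

comm <- default_community()
comm
#> # A tibble: 3 × 9
#>   species_id t_min t_opt t_max r_peak death_slope form      k    n0
#>   <chr>      <dbl> <dbl> <dbl>  <dbl>       <dbl> <chr> <dbl> <dbl>
#> 1 S3             0    32    37      1         0.1 beta      1  0.01
#> 2 S1             0    37    41      1         0.1 beta      1  0.01
#> 3 S2             0    42    46      1         0.1 beta      1  0.01

steady_state(comm, temp = 37)
#> <lv_steady> 3 species at 37 degC; converged at t = 26.6006 (max |dN/dt| = 1e-09)
#> # A tibble: 3 × 4
#>   species_id density relative_density  rate
#>   <chr>        <dbl>            <dbl> <dbl>
#> 1 S3           0.01            0.0100 0
#> 2 S1           0.850           0.850  1
#> 3 S2           0.140           0.140  0.595

sw <- run_temperature_sweep(comm)   # 201 grid points, 25-45 degC
dominance_intervals(sw)
#> # A tibble: 3 × 4
#>   species_id  t_lo  t_hi n_points
#>   <chr>      <dbl> <dbl>    <int>
#> 1 S3          25    34.3       94
#> 2 S1          34.4  39         47
#> 3 S2          39.1  45         60
```

At the 37 °C reference temperature the species whose optimum sits exactly
there (S1) holds 85 % of total density; the cold-adapted S3 is at its
critical maximum (rate 0) and merely holds its initial 1 %. Across the
sweep, dominance hands over from the low-optimum species to the
high-optimum species as the environment warms — S3 below 34.4 °C, S1 up to
39 °C, S2 above — while S1 keeps more than 1 % of total density at every
temperature where it can grow at all. `autoplot(sw)` draws the
density-versus-temperature figure; `tidy(sw)` and `glance(sw)` return the
underlying tables.

The robustness battery is one call:

```r
spec <- scenario_spec(n_draws = 10, seed = 1)
summ <- evaluate_robustness(generate_scenarios(spec))
glance(summ)
```

A YAML-driven command-line interface wraps the same functions:

```sh
exec/thermocompete sweep inst/extdata/default_config.yaml --out out/
exec/thermocompete robustness inst/extdata/default_config.yaml --seed 2 --out out/
```

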