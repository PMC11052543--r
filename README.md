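# amha

Three-state social-contagion analysis of drinking behaviour on a
longitudinal social network.

Alcohol use spreads partly through social ties: people surrounded by heavy
drinkers drink more, people surrounded by abstainers drink less. `amha`
models this as an SIS-type contagion with three states — **A**bstain,
**M**oderate, **H**eavy, classified from self-reported drinks per week at
the NIAAA cutoffs (7/week women, 14/week men) — on an undirected social
network observed over repeated examination waves. Every ordered transition
X→Y, including the direct A↔H "superinfection" jumps, occurs over an
interval Δt with probability

```
P(X -> Y; Δt) = (α_XY + Σ_Z β_XY^Z · N_Z) · Δt
```

where `α_XY` is the spontaneous rate, `β_XY^Z` the social rate per
network neighbour currently in state Z, and `N_Z` the ego's neighbour
count in state Z. The package is aimed at researchers in social
epidemiology and computational behavioural science who want to calibrate,
validate and simulate such models — and, because the motivating cohort
(Framingham-style panel + sociometric ties) is access-restricted, it
includes a fully seeded synthetic generator with known ground truth so
every method is testable end to end without any data download.

What it does:

* **Data model** — state classification, study filters (age > 21, known
  drinking state, coworker/neighbour edges removed), transition
  extraction with neighbour context, CSV/JSON round-trip I/O.
* **Descriptives** — transition/stability matrices, annualization,
  wave-to-wave state correlation, spatial correlation and clustering
  `C_XY` against an exact permutation null, ego–neighbour χ² tests,
  moderate/heavy cutoff sweeps, degree distributions, per-wave summary
  tables.
* **Calibration** — weighted least squares of transition fraction on
  neighbour count (intercept = α, slope = β), cross-influencer terms,
  p ≤ 0.05 retention, logistic-regression agreement check, per-wave trend
  diagnostics.
* **Simulation** — a well-mixed mean-field ODE and a bit-reproducible
  discrete-time stochastic simulator on static networks, plus forecasts
  from an observed wave.
* **Interventions** — multiplicative sweeps of "positive" (toward
  abstinence) and "negative" (toward drinking) social rate sets on a log
  grid, 30-year endemic heavy-drinker fractions with replicate intervals,
  strategy comparison with common random numbers.

## Worked example

```r
library(amha)

sc  <- scenario_config(n_persons = 2000, n_waves = 7, seed = 11)
syn <- synth_scenario(sc)                      # panel + network + ground truth
flt <- apply_study_filters(syn$panel, syn$network)
tr  <- extract_transitions(flt$panel, flt$network)

transition_matrix(tr)
#> Transition matrix (rows: from, columns: to)
#>       A     M     H
#> A 0.780 0.207 0.013
#> M 0.126 0.766 0.108
#> H 0.105 0.234 0.661
```

Rows are origin states, so e.g. a heavy drinker has probability 0.661 of
still drinking heavily one wave (4 years) later; the near-zero A→H entry
shows moderate drinking acting as the gateway state.

```r
spatial_correlation(flt$panel, flt$network)
#> Spatial correlation / clustering C[X,Y] (mean over 7 waves)
#>      A    M    H
#> A 1.20 0.96 1.03
#> M 0.96 0.91 0.98
#> H 1.03 0.98 1.32
```

`C_AA = 1.20` and `C_HH = 1.32` mean abstainers and heavy drinkers are
20% and 32% more likely to be linked to their own kind than random mixing
predicts — the network is assortative, so well-mixed models are not
enough.

```r
params <- calibrate(tr, reference_period_years = 4)
params
#> AMHa rates per 4-year period
#>   A -> M : alpha = 0.1755, beta^M = 0.0221, beta^H = 0.0182
#>   A -> H : alpha = 0.0116
#>   M -> A : alpha = 0.1039, beta^A = 0.0236
#>   M -> H : alpha = 0.0804, beta^H = 0.0509
#>   H -> A : alpha = 0.0792, beta^A = 0.0255
#>   H -> M : alpha = 0.2264
```

The generator's true rates were α = (0.18, 0.01, 0.10, 0.08, 0.25, 0.07)
and β = (0.020, 0.040, 0.025, 0.035) on the corresponding channels: every
true rate is recovered within sampling error. The small extra
`beta^H = 0.0182` on A→M is a genuine property of single-regressor
calibration on an assortative network (heavy- and moderate-neighbour
counts are correlated), kept visible rather than hidden — see the methods
vignette.

```r
fc <- forecast_amha(flt$panel, flt$network, params, wave = 3,
                    horizon_years = 30, replicates = 33, seed = 11)
fc
#> AMHa network simulation: 2000 nodes, 33 replicates, 30 years (dt = 1)
#> Final mean fractions: A 0.348, M 0.483, H 0.168
#> Observed vs simulated fractions at later waves:
#>    wave year obs_A obs_M obs_H sim_A sim_M sim_H
#>       4 1984 0.336 0.479 0.184 0.336 0.487 0.178
#>       5 1988 0.342 0.485 0.172 0.336 0.489 0.174
#>       6 1992 0.354 0.475 0.170 0.340 0.489 0.171
#>       7 1996 0.349 0.482 0.168 0.343 0.488 0.170
```

Forecasting from wave 3 under the calibrated rates tracks the held-out
later waves to within a percentage point. Intervention experiments then
ask which policy lever moves the endemic heavy fraction more:

```r
w3 <- flt$panel[flt$panel$wave == 3, ]
states <- setNames(w3$state, w3$person_id)
cmp <- compare_strategies(flt$network, states, params, factor = 2,
                          horizon_years = 30, replicates = 33, seed = 11)
```

## Command line

```sh
exec/amha pipeline --seed 7 --out runs/demo      # synth -> ... -> intervene
exec/amha simulate --network edges.csv --states states.csv \
    --params params.json --dt 1 --years 30 --reps 33 --seed 1 --out out/
```

Every stage writes plain CSV/JSON plus a manifest with seeds and
checksums; reruns with the same seed are byte-identical.

## Documentation

The methods vignette (`vignettes/amha-methods.Rmd`) describes the model
and its assumptions, every tunable parameter with its default and units,
what the synthetic world does and does not emulate, and the numerical
choices (SE construction, integrator, tie-breaks, probability guards).
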