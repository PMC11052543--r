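---
title: "Modelling drinking behaviour as a three-state contagion on a social network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drinking behaviour as a three-state contagion on a social network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amha)
```

## The model

`amha` treats drinking behaviour as a three-state contagion process on an
undirected social network. Every person at every examination wave is
classified from self-reported drinks per week as abstaining (A), moderate
(M) or heavy (H), using the NIAAA cutoffs of 7 drinks/week for women and 14
for men; zero consumption is abstinence and the threshold itself still
counts as moderate. Because behaviour confers no immunity, the process is
SIS-like: every ordered transition between the three states is allowed,
including the direct "superinfection" jumps A→H and H→A.

Each transition X→Y has a spontaneous component and a social component. Over
a time step $\Delta t$ the transition probability of an individual with
$N_Z$ neighbours currently in state $Z$ is

$$P(X \to Y;\ \Delta t) \;=\; \Big(\alpha_{XY} + \sum_Z \beta_{XY}^{Z}\, N_Z\Big)\,\Delta t,
\qquad P(X \to X) = 1 - \sum_{Y \neq X} P(X \to Y),$$

with $\alpha_{XY}$ the spontaneous rate (cultural drift, policy, personal
circumstances) and $\beta_{XY}^{Z}$ the additional probability per
neighbour in state $Z$. Rates are stored per *reference period* (default 4
years, the panel's typical inter-wave interval) and rescaled linearly to
the simulation step. The linear-in-neighbours law is only valid while all
per-step probabilities stay below one; both the simulator and the
calibrator guard this explicitly and fail loudly rather than truncate.

The well-mixed (mean-field) counterpart replaces neighbour counts by
population fractions: flows $X \to Y$ of size
$X(\alpha_{XY} + \sum_Z \beta_{XY}^Z\, g(Z))$ with, by default, the
per-capita convention $g(Z) = Z/N$, which makes trajectories independent
of population size. To compare a dense-network simulation with the ODE,
either give the network simulator per-neighbour rates $\beta/N$ (per-capita
ODE) or run the ODE with `density = "per_count"`.

## Calibration

Transitions are extracted by comparing each person's state at consecutive
waves, attaching the neighbour-state counts at the origin wave (neighbours
with unknown state are excluded, never imputed). For each of the six
transitions, the fraction of at-risk individuals transitioning is
regressed on the count of neighbours in the destination state:
the intercept estimates $\alpha_{XY}$ and the slope $\beta_{XY}^{Y}$.
Two cross terms are tested by default — heavy neighbours pulling abstainers
into drinking ($\beta_{AM}^{H}$) and abstaining neighbours pulling heavy
drinkers to moderation ($\beta_{HM}^{A}$); any influencer grid can be
configured. A social rate is retained only when its slope is positive with
$p \le 0.05$ (configurable; no multiple-testing correction, matching the
source methodology); negative or non-significant slopes are reported in
the diagnostics but enter the parameter set as zero, because the simulator
requires non-negative rates and the "protective" effect of same-state
neighbours is absorbed by the spontaneous rate.

Two numerical choices deserve note.

* **Weights and standard errors.** The WLS weights are the at-risk counts
  per aggregated neighbour-count cell, which makes the point estimates
  identical to an ordinary least-squares regression of the individual
  binary transition indicators on the count. Standard errors are computed
  on that individual-level equivalence (residual degrees of freedom
  $n-2$, residual variance pooling within-cell binomial scatter and lack
  of fit). Computing the residual variance from the handful of aggregated
  cells instead would leave 3–6 degrees of freedom and make the t
  statistics heavy-tailed; in recovery experiments that inflated the
  spread of the standardized error to 1.7 and produced occasional 9-sigma
  outliers.
* **Single-regressor fits.** Each social term is fitted in its own simple
  regression, mirroring the source methodology. When two influencer
  counts are correlated (through degree and assortative mixing) a term
  can pick up part of another's effect — an omitted-variable effect
  visible in the worked example, where a small spurious cross term
  appears alongside the true rates. This is a property of the method, not
  of the implementation; the package reports every fitted term with its
  standard error so the diagnosis is visible. For the same reason the
  synthetic generator's default truth places at most one social term per
  transition, with the destination state as influencer: under that stated
  world the single-regressor protocol is unbiased and ground-truth
  recovery is a fair test of the code rather than of the protocol.

Because a logistic regression is the natural model for a binary outcome,
`fit_logistic_check()` refits each transition logistically and reports the
maximum per-count divergence of predicted probabilities; at the panel's low
rates and low degrees the two agree to well under 0.02, which is what
justifies the linear reading of intercept and slope as rates.

`per_wave_trend()` refits every transition wave by wave and tests a
weighted linear trend of the estimates over the wave index; a flat,
individually significant spontaneous rate is what justifies pooling all
waves into one calibration.

## Validation statistics

* **Transition matrix** (`transition_matrix`): row-stochastic 3×3 matrix
  of state changes per wave pair; its diagonal is the per-period
  stability.
* **Annualization** (`annualize_stability`): the default converts a
  per-interval stay probability $p$ to $p^{1/\Delta t}$; the alternative
  takes the diagonal of the $\Delta t$-th matrix root of the full
  transition matrix, which accounts for round trips through other states.
  Neither reproduces exactly the yearly values printed in the source study
  (93.8/91.8/90.3% from per-period stays of 0.75/0.67/0.61 at
  $\Delta t \in \{3,4\}$); the formula behind those numbers is not stated
  there, so both methods are provided and the discrepancy is documented
  rather than resolved.
* **Wave-to-wave correlation** (`state_correlation_by_wave`): Pearson
  correlation of the ordinal coding A=0, M=1, H=2 between consecutive
  waves — the simplest reading that makes the published range (0.5–0.7)
  interpretable.
* **Spatial correlation / clustering** (`spatial_correlation`):
  $C_{XY}$ is the observed number of X–Y edges over its expectation under
  random permutation of the observed state labels with the graph held
  fixed, computed analytically
  ($E_{XY} = 2 m\, n_X n_Y / (n(n-1))$ off-diagonal,
  $E_{XX} = m\, n_X(n_X-1)/(n(n-1))$). The permutation null is the
  standard assortativity null and is exactly testable: the test suite
  verifies the analytic expectation against exhaustive label permutations
  on graphs of up to 8 nodes. Cells for states absent at a wave are
  undefined (`NA`), not zero, and multi-wave summaries are unweighted
  means of per-wave matrices.
* **Ego–neighbour independence** (`chisq_state_adjacency`): the 2×3 table
  (ego in focal state vs not) × (neighbour state) over ordered
  ego–neighbour pairs, Pearson chi-squared without continuity correction;
  this construction is what matches the published df = 2 convention.
* **Cutoff sweep** (`stability_cutoff_sweep`): re-classifies the panel
  under a grid of female thresholds (male = 2× female) and recomputes
  annualized stabilities. The "combined" moderate-plus-heavy stability is
  the unweighted mean of the two category stabilities. Two tempting
  alternatives are degenerate: staying within the M∪H superset is
  invariant to the cutoff, and the origin-pooled same-category stay is
  bounded above by the superset stay, hence monotone-saturating in the
  cutoff; only the equal-weight mean can peak at an interior cutoff,
  which is the figure's entire point.

## Simulation and interventions

The network simulator is discrete-time and synchronous: at each step every
node draws its next state from the per-step law with neighbour counts
frozen at the step start, which is exactly the semantics of the per-$\Delta t$
probability formulation (an asynchronous random-order scheme is available
for sensitivity checks). The node set is static — no birth, death or
rewiring — and replicate $r$ of a run seeds the RNG with `seed + r - 1`,
making every run bit-reproducible and enabling common random numbers
across intervention arms. The default step is 1 year; a start-of-run guard
errors if any node's total leave probability would exceed one.

A mean-field check is built into the test suite: on a complete graph of
500 nodes with per-capita rates, the replicate-mean trajectory must agree
with the ODE solution within 3 Monte-Carlo standard errors at every
yearly checkpoint. That comparison is run at a step of 0.1 years: with 200
replicates the Monte-Carlo resolution (~0.004) is finer than the
first-order time-discretisation bias of a 1-year step, so a coarser step
would test the discretisation rather than the mean-field limit. The ODE
itself is integrated with fixed-step RK4 (adaptive RKF45 optional), with
positivity projection and conservation of $A+M+H$ to $10^{-6}N$; the
$\beta = 0$ linear case is verified against the matrix exponential.

Interventions scale named rate sets multiplicatively, preserving relative
proportions within the set: `social_positive` ($\beta_{MA}^{A},
\beta_{HA}^{A}$ — abstainers pulling others toward abstinence),
`social_negative` ($\beta_{MH}^{H}, \beta_{AM}^{H}$ — heavy drinkers
pulling others toward drinking), and the spontaneous analogues. Sweeps run
over a log-spaced multiplier grid (so halving and doubling are
equidistant), simulate 30 years to an endemic state, and summarise the
final heavy fraction across replicates with 2.5/97.5-percentile intervals
— the percentile construction is this package's choice, the source's
interval construction being unstated. Grid points whose multiplier pushes
a step probability above one are flagged and skipped, never truncated.
`compare_strategies()` runs positive-×-factor against negative-÷-factor
with common seeds and reports both arms and their difference without a
hard-coded verdict.

## The synthetic world

Real data of this kind are access-restricted, so the package ships a
generator (`synth_scenario`) whose outputs play the role of the cohort and
whose internals are fully known:

* **Network**: a fixed number of edges ($n \bar d / 2$) sampled with
  probability proportional to products of node fitnesses drawn from an
  exponential truncated at twice its mean. This yields a low, decreasing
  degree distribution with a short tail (max degree a few times the
  mean). The truncation is deliberate: with an unbounded tail, rare hubs
  acquire enough heavy-drinking neighbours that the linear law exceeds
  probability one — outside the regime in which the model is valid, and
  outside the regime the source data occupy.
* **Initial states**: exact marginal counts at the configured fractions
  (default A 0.30, M 0.50, H 0.20, near the cohort's middle waves),
  followed by label-swap annealing on edges until the abstainer and heavy
  clustering reach $1 + s\,(C^{\ast}-1)$ within 0.1, with targets
  $C^{\ast}_{AA} = 1.4$, $C^{\ast}_{HH} = 1.5$ and assortativity strength
  $s \in [0,1]$ (default 1). Assortativity is injected only at
  initialization; any later clustering emerges from the dynamics, which
  mirrors the fact that homophily and contagion are not separable in the
  real panel either.
* **Trajectories**: states advance wave to wave by exactly the
  simulator's law under known true parameters (defaults per 4-year
  period: $\alpha_{AM}=0.18$, $\alpha_{AH}=0.01$, $\alpha_{MA}=0.10$,
  $\alpha_{MH}=0.08$, $\alpha_{HM}=0.25$, $\alpha_{HA}=0.07$;
  $\beta_{AM}^{M}=0.020$, $\beta_{MH}^{H}=0.040$, $\beta_{MA}^{A}=0.025$,
  $\beta_{HA}^{A}=0.035$ — magnitudes in the published range, one social
  term per transition for the reason given above).
* **Covariates**: sex Bernoulli 1/2 fixed per person; age normal around
  the cohort's mid-50s, advancing by the interval; drinks per week drawn
  within the state's band (A: 0; M: uniform 1…threshold; H: threshold +
  1 + geometric), so re-classifying the emitted drinks reproduces the
  states exactly. Within-state drink distributions are otherwise
  arbitrary — only the classification matters downstream.
* **Ground truth**: the generator logs every realized transition with its
  neighbour context; this log is the oracle against which
  `extract_transitions()` and `calibrate()` are tested.

What a green test does *not* establish: the generator has no within-state
drink autocorrelation, no missingness, no cohort entry or mortality, no
directional influence, and its network is static with a single edge type.
Conclusions about those features of real panels are out of reach of this
test suite by construction.

## Degenerate inputs and tie-breaks

Missing drinks or sex leave the state `NA`; such records are excluded by
the study filter and their neighbours do not count toward any context.
Persons absent from the network contribute transitions with zero neighbour
counts. A wave at which a state is absent yields `NA` spatial-correlation
cells. `calibrate()` errors if an origin state has no at-risk records, and
clamps a (rare) negative intercept to zero since rates are probabilities.
The chi-squared test attaches a warning flag when any expected cell is
below 5. All writers emit sidecar JSON metadata so filtered files are
self-describing, and the pipeline manifest records seeds and checksums —
reruns with the same seed are byte-identical at the JSON level.

## Known limitations

The calibration pools repeated observations of the same ego across waves
without a repeated-measures correction (the literal reading of the source
methodology); standard errors are therefore mildly optimistic for long
panels. Single-regressor social terms can absorb correlated influences, as
discussed above. The simulator is discrete-time; a continuous-time
(Gillespie) engine would remove the step-size guard but is not required to
mirror the source results. Non-Markovian relapse dynamics — former heavy
drinkers relapsing at elevated rates — are explicitly out of scope.
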