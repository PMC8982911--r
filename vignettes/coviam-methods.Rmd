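---
title: "Modelling pandemic impacts on SDG indicators: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pandemic impacts on SDG indicators: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coviam)
```

## The modelling problem

`coviam` simulates how the COVID-19 shock propagates through Egypt's economy,
social-protection system and environment, tracked by four headline SDG
indicators over 2015--2050: the share of the population below the national
poverty line (SDG 1), the prevalence of moderate or severe food insecurity
(SDG 2), the total GDP growth rate (SDG 8), and annual greenhouse-gas
emissions in Mt CO2-equivalents (SDG 13).

The package has two layers. The *engine* is a generic stock-flow simulator: a
model is a declarative set of stocks, flows, auxiliaries, lookup tables and
parameters, integrated by explicit Euler over calendar years. The *Egypt
instance* (`build_coviam()`) encodes the published causal-loop structure —
which gives link signs, 2015 initial values and output trajectories, but no
rate equations — so the quantitative equations are this package's own
construction, built from the canonical system-dynamics idiom and calibrated
to the printed trajectory points.

## Goal-seeking structure

Every driven indicator $x$ follows first-order goal adjustment plus signed
couplings:

$$\frac{dx}{dt} = \frac{g_x(t) - x}{\tau_x} + \sum_j s_{xj}\,\Delta_j(t)$$

where $g_x(t)$ is a piecewise-linear goal path (a lookup), $\tau_x$ an
adjustment time in years, and each coupling term is a sensitivity $s_{xj}$
times a deviation $\Delta_j$ of a driver from its 2015 operating point (or,
for the population level, from an expected demographic reference path). The
goal path switches between a *current-path* lookup and a *Vision-2030* lookup
when the policy scenario activates in 2022. Goal-gap adjustment is the
canonical way to express managed indicators in system dynamics: it yields the
smooth approach curves that annual policy indicators show, and it leaves
every free constant calibratable against printed trajectory values.

Deviation-from-baseline couplings deserve a note: they linearise each
influence around the 2015 operating point, so all coupling terms vanish at
the base year by construction and grow as the system departs from it. This
keeps the couplings honestly signed (each carries the polarity the
causal-loop narrative assigns) while leaving the calibrated goal knots able
to absorb their slow drift along the projection path.

## Stocks, couplings, and the feedback inventory

Stocks: `population` (persons), `below_poverty_pct`, `food_insecurity_pct`,
`econ_strength` (the underlying sustainable growth rate, in percentage
points), `inflation_pct`, `ghg_trend` (Mt CO2-eq/yr), `climate_action_score`
(dimensionless 0--1) and `ghg_cumulative`. Percentages are carried on the
0--100 scale throughout.

The couplings realise the narrated loop signs: deaths raise the average
mortality rate and drain the population; a smaller population lowers GDP
growth; lower growth cuts essential-service spending and access, raising
service-lack deaths (reinforcing), while counter-cyclical social protection
expands and damps disaster deaths (balancing); inflation erodes purchasing
power (lowering growth) and pushes both the food-price-anomaly index and the
poverty share upward; falling unemployment strengthens the economy. Each
dependency carries an explicit sign annotation in the model specification, so
`extract_causal_graph()` recovers a signed digraph and
`audit_expected_loops()` verifies the 18-loop inventory
(`coviam_expected_loops()`): B1--B7 balancing, R1--R11 reinforcing.

Three routing choices in that inventory were genuinely open and are this
package's own resolution. The narrative describes two of the
mortality-rate variants with identical wording, so R3 is routed through
government spending *and* access while R6 uses the direct growth-to-access
link, keeping all 18 node sets distinct. R11 (the unemployment–economy
variant) is routed through the social-protection closure: under the stated
link signs, any cycle combining the unemployment detour with a
poverty-closure has an odd number of negative links and would classify as
balancing, whereas the social-protection closure yields the reinforcing
polarity the inventory requires. The loop audit collapses pass-through nodes
(flow variables, the three access components, the population-deviation
helper) out of each enumerated cycle before node-set comparison; the
polarity is always the full cycle's sign product, which pass-through chains
preserve.

## The COVID-19 shock and the policy scenario

The pandemic enters as exogenous overlays on four shock inputs, all zero in
the baseline run (so zero shock magnitudes reproduce the baseline bitwise):

* `covid_gdp_gap` — a unit step on [2020, 2022) that suppresses the GDP
  growth indicator (and the economic-strength goal) toward the contracted
  level `gdp_covid_level`;
* `covid_excess_mort` — an excess-mortality addition on [2020, 2022);
* `ghg_lockdown` — a fractional emission cut on [2020, 2021) only; the 2021
  rebound is deliberately *not* an explicit positive shock — the suppression
  simply ends and economy-coupled emissions resume;
* `covid_food_stress` — a food-system stress term (%/yr) on [2020, 2022).

Windows are half-open: a step on [2020, 2022) is active at t = 2020 and 2021
and off at 2022. The Vision-2030 scenario is a single switch overlay from
2022 onward that flips every goal lookup from its current-path to its
Vision levels (poverty declining to the mid-teens, food insecurity to full
sufficiency — modelled as a goal of exactly 0% by 2049, with the
non-negativity floor absorbing coupling wiggle — growth recovering, and
emissions on a Paris-aligned decline). Composition is explicit
(`compose_scenarios()`); two scenarios overriding the same input is an
error, never a silent last-wins.

## Numerical choices

* **Integration**: explicit Euler, default dt = 1 year. Indicators are
  annual; "value in year Y" is the trajectory sample at t = Y. The step is
  configurable, and the suite checks first-order convergence under dt
  halving as well as exact agreement with the closed-form Euler recurrence
  on a decay model.
* **Adjustment times**: default $\tau = 1$ year for the four headline
  indicators (annual goal revision), 2 years for inflation, 8 for the slow
  climate-capacity score. With $\tau = dt = 1$ the Euler update tracks the
  goal path with a one-year lag, which makes the goal knots directly
  identifiable from the anchors.
* **Expression safety**: model equations are parsed and validated against a
  closed grammar (arithmetic, comparisons, `min`, `max`, `abs`,
  `if_then_else`, `lookup`, literals, `t`) and evaluated in a sealed
  environment containing only those operators; division by zero is an error,
  not an `Inf`.
* **Degenerate states**: non-negative stocks (population, percentages,
  emissions) are floored at 0 with a logged warning rather than silently
  allowed — calibration must not be able to exploit unphysical states. Bounded
  reporting auxiliaries clamp to [0, 100] (or [0, 1]) via `min`/`max`.
* **Determinism**: identical inputs produce bitwise-identical trajectories;
  every stochastic element (synthetic-anchor noise, calibration restarts) is
  seeded.

## Calibration

The printed material fixes the trajectory, not the equations, so the
quantitative content of calibration is *joint consistency*: one parameter
vector, under the fixed loop structure, must pass through all fourteen
packaged anchors (four poverty points, one food-insecurity point, five
growth points, four emission points) in a single run of the
COVID + Vision-2030 scenario. That is a falsifiable requirement — fourteen
anchors against thirteen free constants — not an out-of-sample prediction,
and the package states it as such.

The free parameters (`coviam_free_parameters()`) are the goal-knot levels
and the two shock constants in near one-to-one correspondence with the
anchors; this makes them identifiable, which the parameter-recovery tests
exercise: on noiseless synthetic anchors the optimiser recovers known values
to better than 1% relative error. Adjustment times and coupling
sensitivities are *not* identifiable from the anchor set (many combinations
reproduce the same fourteen points) and are therefore held at documented,
field-plausible defaults rather than fitted. The optimiser is derivative-free
bounded local search — Nelder-Mead on a logistic transform of the box — with
a seeded multi-start (default start plus uniform draws) and a final polish,
chosen because one objective evaluation is a single 36-step simulation
(milliseconds) and the objective can be non-smooth at stock floors. Weights
in the packaged anchor set are inverse squared tolerances, so the objective
is scale-free across indicators measured in percentage points and megatonnes.

Anchor tolerances derive from the source's own precision language: exactly
printed values carry ±1% relative tolerance, values qualified as
"around"/"approximately" carry ±5%. Two conflicting 2015 prints (poverty
27.5 vs 27.8; emissions 240 vs 264.9) are resolved by initialising stocks
from the variable table and keeping the narrative figures as labelled
alternates — deliberately *not* anchors. Likewise the simulated growth
indicator is total GDP growth (4.37% in 2015); the per-capita figure (5.43%)
is carried as metadata only.

## What the synthetic-data generator does and does not show

`synth_anchors()` draws anchors as simulated indicator values plus
independent Gaussian noise of stated spread, seeded. It emulates the
measurement situation the calibration layer faces — sparse, noisy point
observations of smooth annual indicator paths — and supports the
parameter-recovery tests. It does not emulate real SDG statistics'
autocorrelated revisions, reporting lags, or definitional breaks; a passing
recovery test therefore certifies the optimiser and the identifiability of
the freed constants, not the model's adequacy for real Egyptian data.

## Population scale

No population level is printed in the source material, so the model carries
`population_2015` (default 9.3e7, an external convention) whose absolute
level cancels out of every fraction-valued indicator: couplings use the
deviation of population from its expected demographic reference path, and
social-protection coverage converts person counts to a share of the
simulated population. Tests never depend on the absolute level.

## Problem sizes used by the tests

The suite runs the full model (36 annual steps, ~54 variables) for scenario
and acceptance checks; property tests use small fixtures — a one-stock decay
model for integrator exactness and rate recovery, random signed digraphs of
up to 8 nodes against a brute-force circuit enumerator (25+ graphs), 1000
seeded draws for the synthetic-noise spread, and two-parameter recovery
problems for the Egypt instance. A full calibration (four restarts, 250
simplex iterations each) takes under a minute on one CPU.

## Known limitations

* The quantitative equations are reconstructions; only their signs, initial
  values and the printed trajectory points are sourced. Any use beyond
  reproducing those trajectories (e.g. genuine counterfactual policy
  analysis for Egypt) would need re-estimation against real data.
* The full published causal diagram contains 52 loops (26 positive, 26
  negative); only the 18 loops narrated in text are reconstructible and
  audited. The 52/26/26 totals are documented but not testable, and the
  shipped graph's own loop count (58 elementary cycles, including the
  goal-seeking minor loops the stock-flow translation adds) is not
  comparable to the diagram's.
* Epidemiological dynamics are out of scope: COVID-19 is an exogenous shock
  window, not a transmission model.
* Euler at dt = 1 year is a convention; the source's simulation settings are
  unstated. First-order accuracy is adequate for goal-tracking dynamics but
  the engine deliberately offers no higher-order integrators.
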