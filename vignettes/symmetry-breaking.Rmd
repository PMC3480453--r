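---
title: "Choice rules, pheromone trails and symmetry breaking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choice rules, pheromone trails and symmetry breaking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`antsym` simulates a colony of ants foraging at identical food patches
connected to the nest by pheromone trails, and measures when the colony's
effort collapses onto a single patch — *symmetry breaking*. This vignette
is the package's account of the model, its assumptions, the parameters
that matter, and the design decisions taken where more than one reasonable
implementation exists.

## The model

Time advances in discrete steps (about 5 s of real foraging each). Each
step, in order:

1. **Departures.** Every ant in the nest leaves with probability
   `p_leave` (default 0.01). Each leaver immediately samples one of the
   `n_trails` (default 4) trails from the preference distribution of the
   configured choice rule, evaluated on the pheromone amounts current at
   the start of the step.
2. **Travel.** Outbound ants advance along an 18-step path
   (`travel_steps`); feeding ants advance through 6 feeding slots
   (`feed_steps`); homeward ants advance along an 18-step return path
   (`return_steps`).
3. **Patch admission.** Arrivals enter the patch up to its free capacity
   (`patch_capacity`, unlimited by default; 15 for "small" patches).
   Excess arrivals turn straight back, flagged unsuccessful.
4. **Feeding completions** start the walk home, flagged successful.
5. **Nest arrivals** rejoin the pool and may leave again from the next
   step. Only successful foragers lay pheromone (see below); the random
   null rule lays none.
6. **Evaporation.** Every trail's pheromone is multiplied by
   `1 - decay` (default decay 0.1) after all behaviour of the step.

Ants are interchangeable, so the engine tracks counts per queue slot
rather than individuals; a 1000-step run costs a few milliseconds in the
compiled core, and a pure-R reference step (`sim_step()`) consumes the
random stream identically so the two implementations can be compared
bit-for-bit in the tests.

With the default rates the expected round trip is 18 + 6 + 18 = 42 steps
against a mean nest wait of `1 / p_leave` = 100 steps, so a fraction
42/142 ≈ 0.296 of the colony — between 25% and 30% — is outside the nest
at any time. This "active forager number" (≈ 0.3 × colony size) is the
natural x-axis for colony-size effects.

## Choice rules

Given pheromone amounts `c_i`, a departing forager's preference for trail
`i` is:

| rule | preference | notes |
|---|---|---|
| random | `1/s` | null model; never lays pheromone |
| linear | `c_i / Σ c_j` | proportional response |
| sigmoidal | `(k + c_i)^x / Σ (k + c_j)^x` | `k` = intrinsic trail attractiveness, `x` = steepness |
| ranked | strongest w.p. `p_top`, then recurse | most extreme non-linearity |

The linear rule is exactly the sigmoidal rule with `k = 0, x = 1` (an
identity the tests assert). For `k = 0` the sigmoidal preference depends
only on pheromone *proportions* and is scale invariant; for `k > 0` the
*amount* matters, so the effective non-linearity grows as pheromone
accumulates — which couples these rules to colony size.

The ranked rule assigns positional masses `p_top`,
`(1 − p_top)·p_top`, …, with the last trail receiving the residual
`(1 − p_top)^(s−1)`. Ties (exactly equal strengths, or trails grouped by
the discrimination step) share the mean of their block's positional
masses, which equals averaging over all strict orderings of the tied
trails. An alternative reading of the "error rate" — strongest with
`p_top`, remainder split uniformly — is available as
`error_mode = "uniform"`; the recursive form is the default because the
recursion is the explicit description of the decision process. A
brute-force enumeration of the decision tree serves as the test oracle
for both tie handling and the recursion.

**Degenerate inputs.** If every weight is zero (all trails at zero
pheromone under linear, or `k = 0` with all-zero trails) the preference
falls back to uniform — the state of a colony before any recruitment.

## Discrimination between trails

Real ants cannot distinguish trails that differ by tiny amounts of
pheromone. `apply_discrimination()` implements a minimum detectable
difference `d`: trails are sorted and chained into groups wherever the
gap between adjacent sorted values is strictly less than `d`
(single-linkage). "Indistinguishable" is not transitive, so some
convention is required to obtain a partition; single-linkage chaining is
deterministic and errs on the side of coarser perception. Group members
are assigned the group's arithmetic-mean strength (so proportional rules
treat them as equal) and are tied for the ranked rule. `d = 0` is the
identity.

## Scoring a run

A run is scored over its trailing `analysis_window` steps (900 of 1000 by
default; recruitment dynamics need some tens of steps to establish, and
excluding the first 100 keeps the start-up transient out of the score).
The share `a` of window departures that chose the most-chosen trail
(determined within the same window; ties to the lowest index) is
standardized to

\[ A = \frac{a - 1/n}{1 - 1/n} \in [0, 1], \]

which is comparable across numbers of food sources: a uniform profile
gives `A = 0` and a single-source profile `A = 1` for any `n`. Departure
choices are used rather than patch arrivals (the same counts lagged 18
steps) to avoid edge effects at the window boundary. A window with no
choices at all yields a *missing* `A`, not 0, so inactive tiny-colony
runs do not drag aggregates toward symmetry.

## Pheromone deposition: a design decision

Successful foragers lay `deposit` (default 0.02) pheromone units per time
step of the homeward walk — 0.36 units per completed trip
(`deposit_timing = "walk"`). An alternative, a single 0.02-unit deposit
on reaching the nest (`deposit_timing = "nest"`), is retained as an
option. Homeward trail-laying is the default for three reasons:

* it is how trail-laying ants actually deposit — continuously along the
  trail while walking home from a profitable source;
* a single lump deposit arriving 42 steps after the choice decouples the
  recruitment feedback from the ~10-step pheromone memory
  (`1 / decay`), so trail leadership echoes and flips for hundreds of
  steps; laying spread along the return closes the loop at the pheromone
  timescale, and the ranked rule then holds its winner so that mean `A`
  equals the transformed set preference `(p_top − 1/n)/(1 − 1/n)` — a
  relationship the acceptance tests verify across `p_top` from 0.4 to
  0.9;
* per-trip totals of order 0.4 let trail pheromone accumulate to tens of
  units in large colonies, the scale at which intrinsic attractiveness
  values `k` of 2–20 start to interact with the signal. With lump
  deposits the total trail signal saturates near 3 units and `k = 20`
  rules would remain uniform at every feasible colony size, contrary to
  the characteristic rise of their asymmetry with forager number.

Pheromone has no ceiling and no floor other than 0. Unsuccessful
(turned-back) ants traverse the full return path and lay nothing.

## Experiments and statistics

`run_sweep()` executes a grid of cells × replicates with per-run seeds
derived deterministically from `(base_seed, cell, replicate)`, so tables
are reproducible and independent of execution order. Presets cover the
standard designs: the eight-rule comparison, `k`- and `x`-sweeps,
discrimination (`d` = 0–5 over 20 colony sizes 5–200), patch capacity
15 vs unlimited, decay sensitivity, and the ranked-preference sweep.

The default colony-size grid is 25 log-spaced integers from 5 to 2000
(average active forager numbers ≈ 1–600), chosen to resolve the
small-colony regime where thresholds live. Pooled medians and fitted
trends depend on this spacing — a grid with more mass at large colonies
shifts pooled statistics of any size-dependent rule — so every sweep
accepts its own `colony_sizes`.

Because `A` is bounded and typically non-normal, rules are compared to
the random-choice null non-parametrically: `null_envelope()` (empirical
95th percentile per size, linear interpolation of order statistics),
`compare_to_null()` (Wilcoxon rank-sum), `detect_threshold()` (first
colony size whose asymmetry exceeds the null, one-sided α = 0.05) and
`capacity_divergence()` (where capacity-limited runs fall below unlimited
ones, and where they converge with the null). Directions of the
asymmetry–forager-number relationship use ordinary least squares
(`asymmetry_trend()`), calling a direction only when `p < 0.05`.

## Problem sizes used in tests

The packaged test-and-acceptance runs use 20 replicates per cell (the
built-in presets default to 100, and 500 for the discrimination design),
which resolves pooled medians to roughly ±0.02 and keeps a full suite run
to a couple of minutes. The capacity check runs the three largest colony
sizes only, where the damping is expected.

## What the simulations do and do not show

The generator *is* the model under study, so tests exercise the actual
object of interest rather than a surrogate; but conclusions remain about
this idealized system: four identical, simultaneously discovered
patches, fixed travel times, no individual memory of food locations, no
spatial trail geometry or crossing, no per-ant heterogeneity in rule
parameters, and recruitment by a single scalar signal per trail. Real
colonies violate all of these in interesting ways.

Two behaviours of the implemented dynamics are worth knowing when
comparing against other implementations of the same scheme:

* With decay 0.1, the pheromone stock on an unreinforced trail decays by
  ~96% between the trips of a near-solitary forager, so at very small
  colonies (≲ 20 ants) a single "error" trip can dethrone the leading
  trail. Strongly proportional rules (`k = 0`) re-lock immediately and
  score `A ≈ 1` there, while the ranked rule's frequent errors produce
  leadership churn and pull its small-colony asymmetry below the
  transformed-preference value it attains from ~60 ants upward.
* The strongly non-linear rules (`k = 0`, `x ≥ 2`) usually lock onto one
  trail well inside the 1000-step horizon, so their scored asymmetry sits
  near the index ceiling of 1 and the `x`-sweep's pooled medians saturate
  beyond `x = 3`.

Both are consequences of the stated constants (decay, trip timing,
window), not tunables of the analysis layer.
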