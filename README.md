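# antsym

Individual-based simulation of **symmetry breaking** in ant foraging: the
emergence of strongly unequal exploitation of *identical* food sources from
stochastic fluctuations amplified by pheromone-trail recruitment.

Many trail-recruiting ants focus almost all foraging on one of several
equally good patches, while honeybees — whose response to recruitment is
linear — do not. `antsym` is for behavioural ecologists and
collective-behaviour modellers who want to dissect *which individual-level
decision rule* produces that colony-level pattern, and how it interacts
with colony size, sensory discrimination limits and patch size.

## The model

A colony of `N` potential foragers exploits `s = 4` identical patches over
1000 discrete time steps (one step ≈ 5 s). Each step, every ant in the
nest leaves with probability 0.01, picks a trail by a choice rule, walks
18 steps out, feeds 6 steps (patches may cap simultaneous feeders), walks
18 steps home, and — if it fed successfully — lays pheromone on its trail
on the way back. Every trail loses 10% of its pheromone per step.

Choice rules, from linear to extremely non-linear (with `c_i` the
pheromone on trail `i`):

* **random** (null model): `prob_i = 1/s`, no pheromone laid;
* **linear**: `prob_i = c_i / Σ_j c_j`;
* **sigmoidal**: `prob_i = (k + c_i)^x / Σ_j (k + c_j)^x` — `k` is the
  intrinsic attractiveness of a trail, `x` the steepness of the response;
  `k = 0, x = 1` is exactly the linear rule;
* **ranked**: take the strongest trail with probability `p_top = 0.75`,
  otherwise recurse on the rest (a 25% "error rate").

A discrimination threshold `d` can blur the input: trails whose strengths
differ by less than `d` are treated as equal (averaged, or tied in rank).

Each run is scored by the **asymmetry index** over the last 900 steps:

    A = (a − 1/n) / (1 − 1/n)

where `a` is the share of departures that chose the most-used of the `n`
sources — `A = 0` is perfectly even foraging, `A = 1` a single trail.

## A worked example

```r
library(antsym)

cfg <- sim_config(500, rule = choice_rule("ranked"), seed = 42)
sim <- run_simulation(cfg)
sim
#> <ant_sim> ranked p=0.75 rule, 500 ants, 1000 steps
#>   asymmetry A = 0.660 (a = 0.745, preferred trail 3)
#>   mean active foragers = 148.3 (29.7% of colony)
```

The colony locked onto trail 3: 74.5% of departures in the scored window
chose it — almost exactly the rule's set preference of 0.75 — giving
`A = 0.66`, the transformed value of that preference. About 30% of the
ants are outside the nest at any time, as the 42-step round trip against
the mean 100-step nest wait implies (42/142 ≈ 0.296).

Sweeps return tidy tables that pipe straight into the analysis layer:

```r
library(dplyr)
null  <- run_sweep(preset_sweep("null",   replicates = 20))
rules <- run_sweep(preset_sweep("rules8", replicates = 20))

summarize_sweep(rules)                      # medians, quantiles, trends
plot_asymmetry(rules, null_envelope(null))  # A vs forager number + null
detect_threshold(filter(rules, rule_label == "ranked p=0.75"), null)
```

`autoplot()` on a single run shows the per-trail pheromone race;
`tidy()`/`glance()` give broom-style access to records and summaries. A
thin command-line front end (`inst/cli/antsym.R`) exposes `simulate`,
`sweep`, `analyze` and `presets` over YAML configs with full manifests.

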