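# herdlab

Tools for studying collective search and division of labor in a
three-player "desert herding" task: a headless multi-agent simulator with
scripted player policies, plus the complete behavioral measurement
pipeline — detrended fluctuation analysis (DFA) of movement-fluctuation
series, alpha-shape search-area overlap, and censored log-logistic
accelerated failure time (AFT) modeling of trial duration.

The package is for researchers in collective behavior, team cognition, and
movement science who want a fully reproducible, human-data-free testbed
for these measures: every analysis the pipeline offers can be exercised on
simulated trials whose generating structure is known and seeded.

## The task

Three avatars on a 500 x 500 m plane must locate, corral, and contain 9 or
18 target agents (TAs) inside a 10 m diameter central containment area. A
TA is a 1 kg agent driven by a uniform random 0–60 N force redrawn at
1 Hz, repelled from any avatar within 10 m with force `min(450, 450/d)` N,
speed-capped at 10 m/s, and damped by linear drag. A trial succeeds when
all TAs stay contained for 5 continuous seconds, and otherwise fails at
the 300 s ceiling. The state is logged at 90 Hz. Scripted policies emulate
the task's information manipulations: visibility (fog = 10 m sensing
radius vs. clear = 150 m) and HUD vs. compass (global vs. local
information), plus search strategy (partitioned sectors, a shared communal
route, random walk, nearest-target corralling).

## The measures

* **DFA scaling exponent** (`dfa_alpha`). For a fluctuation series x(t) —
  here the 5 Hz displacement angle `atan2(Δy, Δx)` or the wrap-aware
  head-orientation change — the profile `Y(k) = Σᵢ≤k (xᵢ − x̄)` is windowed
  at sizes growing from 5 samples by a factor 1.2 up to 10% of the series
  length (50% overlap), linearly detrended per window, and the mean
  residual SD F(w) regressed as `log₁₀ F(w) ~ log₁₀ w`; the slope is
  DFA α. α ≈ 0.5 is uncorrelated noise, α < 0.5 antipersistent, α ≈ 1
  pink-noise structure, α ≈ 1.5 Brownian persistence.
* **Proportion of overlapping search area** (`overlap_proportion`). Each
  player's search polygon is the tightest single-component alpha shape
  containing its trajectory (convex hull as fallback); the measure is
  `area(≥ 2 players) / area(≥ 1 player)` — 0 for a cleanly partitioned
  search, 1 when everyone searched the same ground.
* **Log-logistic AFT** (`fit_aft`). `log T = Xβ + σε` with logistic ε;
  successes are events, 300 s failures are right-censored. Survival curves
  are `S(t|x) = 1 / (1 + (t / e^{xβ})^{1/σ})`.

## Worked example

```r
library(herdlab)

cfg  <- world_config(n_targets = 9)                       # study defaults
team <- replicate(3, policy_config(strategy = "partitioned_sweep",
                                   sense_radius = 150,    # clear visibility
                                   global_info  = TRUE),  # HUD emulation
                  simplify = FALSE)
trial <- run_trial(cfg, team, seed = 7)
trial
#> <herd_trial_log> 12230 samples at 90 Hz | 9 TAs | outcome: success | duration: 135.9 s | seed: 7

dfa_alpha(prepare_angle_series(trial, player = 1, "displacement_angle"))
#> <herd_dfa> alpha: 1.14 | windows: 15 (5-64) | n: 674 | fit R2: 0.993

dfa_alpha(prepare_angle_series(trial, player = 1, "head_orientation_change"))
#> <herd_dfa> alpha: 0.5708 | windows: 15 (5-64) | n: 674 | fit R2: 0.981

trial_overlap(trial)
#> <herd_overlap> proportion: 0.2883 | overlap: 7379.26 | total: 25596.5
```

This informed, sector-partitioned team contains all nine TAs in 136 s.
Player 1's displacement-angle exponent (1.14) reflects strongly persistent,
prospective movement; the head-orientation exponent (0.57) sits near
uncorrelated scanning. The team overlapped on 29% of its searched ground.
Batches over the full 2 x 2 x 2 manipulation design, per-cell bootstrap
summaries, and qualitative direction checks are provided by
`experiment_plan()` / `run_experiment()` / `summarize_experiment()` /
`direction_checks()`, and `fit_aft()` relates the per-trial DFA exponents
to completion time. A thin command-line front end lives at
`inst/scripts/herdlab.R` (subcommands `simulate`, `dfa`, `overlap`,
`experiment`).

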