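---
title: "herdlab: simulator and measurement methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{herdlab: simulator and measurement methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdlab)
```

`herdlab` is a headless reimplementation of a three-player collaborative
search-and-corral game ("desert herding") together with the measurement
pipeline used to quantify team division of labor and the temporal structure
of individual search behavior. This vignette documents the model, every
tunable that matters, the numerical choices, and what the synthetic data
can and cannot stand in for.

## The task and its physics

Three avatars must locate, corral, and contain a set of autonomous target
agents (TAs) inside a 10 m diameter containment area at the center of a
500 x 500 m plane. A trial succeeds when every TA has been inside the
containment area for 5 continuous seconds; any single-frame exit resets the
hold timer. Otherwise the trial fails at the 300 s ceiling and its duration
is recorded as 300 s (and treated as right-censored downstream).

TA dynamics, integrated by semi-implicit Euler at a fixed 90 Hz:

* **Brownian drive.** Each TA (1 kg) receives a random planar force with
  magnitude uniform on [0, 60] N and uniform direction, redrawn at 1 Hz and
  held in between.
* **Avatar repulsion.** An avatar within 10 m pushes the TA directly away
  with magnitude `min(450, 450 / d)` N at distance `d` meters. The
  original game documents this force only as inversely proportional to
  distance with a 450 N maximum; the single-parameter law `c/d` with
  `c = 450` N·m is the minimal reading, with the cap engaging at and below
  1 m. At exactly zero
  distance the direction is undefined and the force is emitted along +x at
  the cap.
* **Drag.** Linear drag `-gamma * v` with `gamma = 20` 1/s by default.
  The original game engine applies drag implicitly and never states its
  value, so this is the one genuinely free physical constant in the
  reimplementation. It was calibrated once, before any measurement work,
  against a playability requirement: unperturbed TAs should wander
  diffusively at walking-like speeds (about 1.5 m/s under the mean 30 N
  kick) and a competent team must be able to hold the containment area for
  5 s. With `gamma` near 1 the Brownian kicks alone saturate every TA at
  the 10 m/s speed cap — a contained TA crosses the 5 m containment radius
  in under a second — and no team, scripted or human, can ever satisfy the
  success condition, which would make the task's own success semantics
  untestable. The knob remains configurable for sensitivity work.
* **Caps and walls.** TA speed is capped at 10 m/s by rescaling the
  velocity after integration (equivalent steady state, order-independent);
  positions are clamped to the arena with the outward velocity component
  zeroed.

Avatars move kinematically at exactly 10 m/s (5 m/s in slow mode) with no
collision physics: the original game specifies avatar speeds, not avatar
dynamics. Containment membership is a closed disc test on the TA center,
and containment takes precedence over the "fleeing" status when both apply.

Spawns are area-uniform over discs around the containment center (radius
100 m for avatars, 180 m for TAs), with no exclusion zone — nothing in the
source material suggests one.

## Scripted players

The three players are scripted stand-ins for human teams. They are not
models of human cognition; their design goal is to produce trial logs with
the same schema and the same *qualitative* condition effects that the
human study reported, so the measurement pipeline can be exercised end to
end. Four phases, in priority order:

1. **Flock shepherding.** Once every target is accounted for near the
   containment area, players split the plane into three 120-degree sectors
   and each escorts the outermost TA of its sector inward, releasing when
   the TA will coast (under drag) to within about 1.2 m of the center, and
   retreating to a post 12.5 m from the center — outside the 10 m repulsion
   radius of centrally contained TAs — so idle guards do not stir the
   flock. This retreat radius matters: a ring of three static guards inside
   repulsion range is an unstable configuration whose pairwise gaps
   actively expel TAs.
2. **Corralling.** A visible uncontained TA is approached from its far
   side relative to the containment area (orbiting around it rather than
   shoving it outward when approached from the wrong side) and pushed
   inward from a 2.5 m tracking point. With global information all players
   compute the same greedy player-TA assignment from the shared distance
   matrix, emulating coordinated target allocation without explicit
   communication. Navigation detours around the containment area so
   players do not barge through it.
3. **Guarding.** Guard duty scales with the contained flock (one guard,
   then two, then all three at the endgame). Fetchers leave
   near-containment escapees to guards and keep retrieving field targets —
   the retriever/guard role split observed in human teams.
4. **Search.** `partitioned_sweep` draws waypoints in the player's own
   sector; `shared_sweep` walks a communal absolute waypoint route (all
   players consume the identical seeded sequence); `random_walk` and
   `corral_nearest` roam the spawn disc. With global information players
   plan long legs anywhere in the field; without it, search is reactive —
   short legs scaled by the sensing radius, redirected far more often.

Two information-dependent noise channels make the *structure* of movement
respond to the task manipulations the way the human data did:

* **Movement jitter** (`move_noise_sd`): Gaussian jitter on the commanded
  movement direction at every control tick, defaulting to 0.04 rad with
  global information and clear sight and growing to about 0.34 rad under
  fog without a HUD. This operationalizes the loss of prospective movement
  control: poorly informed players steer reactively, which lowers the
  persistence (DFA exponent) of their displacement-angle series.
* **Head scan**: head orientation is movement heading plus a sinusoidal
  scan (amplitude 0.6 rad, period 2 s, per-player phase offsets) plus
  0.05 rad Gaussian noise. These values are explicitly synthetic; they
  exist to give the head-orientation channel nondegenerate structure.

Controls are recomputed at 10 Hz and held between ticks — a human-like
control bandwidth that also keeps the event loop affordable — while the
physics always steps at 90 Hz.

The task manipulations are emulated as sensing parameters: fog as a 10 m
sensing radius versus at least 150 m for clear visibility; HUD versus
compass as `global_info` (all entity positions versus own heading only).
The containment-area location is always observable, because the original
game provided it as a landmark in both information conditions; the count of
currently contained TAs is also always observable, standing in for the
verbal count that human guards communicated to their teammates.

## Reproducibility

Every trial takes one root seed and derives independent named substreams
(spawning, Brownian kicks, each player's waypoints and noise) by integer
hashing, so identical `(config, policies, seed)` give bit-identical logs
and swapping one player's policy does not perturb the randomness seen by
the others. Trial logs round-trip exactly through their CSV + JSON-manifest
representation (`%.17g` formatting).

## Fluctuation series

Both analysis series are built at 5 Hz after decimation (every 18th sample
of the 90 Hz log, no filtering — the retained samples are actual logged
states) and deletion of the first second:

* **Displacement angle**: `atan2` of the step vector between adjacent
  positions, in (-pi, pi], analyzed as raw angle levels without
  unwrapping. A stationary frame leaves the angle undefined; the package
  holds the last defined angle (0 before any motion) rather than emitting
  an artificial jump, and `zero_policy = "zero"` is available as the
  alternative.
* **Head-orientation change**: wrap-aware smallest signed difference of
  adjacent head orientations.

A full failed trial yields 27,000 log rows, 1,495 retained samples, and
series of length 1,494.

## DFA

The scaling exponent is estimated exactly as the pipeline under study
specifies: subtract the mean and integrate; window the profile with sizes
growing geometrically from 5 samples (1 s) by a factor 1.2 up to the
largest size strictly below 10% of the series length (nearest-integer
rounding, deduplicated); place windows with 50% overlap (step
`floor(w/2)`, trailing partial window discarded); detrend each window by a
least-squares line; summarize the per-window residual SDs at each size by
their arithmetic mean; and take the OLS slope of log10 fluctuation on
log10 window size.

Numerical choices worth knowing:

* The per-size summary is the *mean of SDs*, matching the procedure's
  wording; the more common root-mean-square convention is available via
  `dfa_config(statistic = "rms")`. Calibration passes under the default.
* Detrending is linear by default (`detrend_order = 1`), the reading
  consistent with the pipeline's own illustration; the order is
  configurable.
* Series shorter than 50 samples are rejected ("insufficient length"), so
  the largest admissible window strictly exceeds the smallest; constant
  series are rejected rather than producing `log(0)`.
* The regression uses base-10 logs; the slope is base-invariant.

Calibration (checked in the test suite at n = 1495 over 50 seeds):
iid Gaussian noise recovers alpha near 0.5, spectrally synthesized 1/f
noise near 1.0, integrated white noise near 1.5, and first-differenced
white noise falls well below 0.5. A spectral-synthesis family with
exponents between these anchors is recovered monotonically.

## Search polygons and overlap

A player's search area is the tightest single-component polygon containing
its (5 Hz, first-second-trimmed) positions. The implementation computes
the Delaunay triangulation (`deldir`) and keeps the alpha complex — the
triangles with circumradius at or below a threshold — for the smallest
threshold under which every input point remains a vertex and the kept
triangles form one edge-connected component. Because the complex is
piecewise constant in the threshold, the candidate set is exactly the
sorted triangle circumradii and an exact binary search replaces the
iterative tolerance-based tightening described for the original toolbox;
it cannot fail to converge, and when only the full triangulation qualifies
the result *is* the convex hull, which is also the documented fallback
whenever the triangulation itself fails on degenerate input (long exactly
collinear trajectory runs; a deterministic sub-micrometer jitter retry
comes first). Holes are permitted and subtracted from the area.

The team measure is the area covered by at least two players' polygons
(union of pairwise intersections — triply covered ground counts once)
divided by the area of the union of all three. Boolean operations use
exact integer-grid polygon clipping (`polyclip`); areas come from the
kept-triangle sum (and agree with the shoelace area of the merged boundary
to well below the clipper's ~1e-9 relative resolution, which is the reason
area assertions in the tests use 1e-6 tolerances rather than exact
equality).

## Survival model

Trial duration is modeled with a log-logistic accelerated failure time
model: `log T = X beta + sigma * eps` with standard logistic errors.
Successful trials are events; trials that hit the 300 s ceiling enter as
right-censored at 300 s — the source material does not state whether
failed trials were censored or treated as exact, and censoring is the
standard treatment for a duration ceiling. The likelihood and its analytic
gradient are implemented directly; fitting uses BFGS from three dispersed
starts (intercept from the log median, scale from an IQR heuristic), with
standard errors from the inverse numerical Hessian. Cluster-robust
(sandwich) standard errors by team are reported when a `team` column is
present — a deliberately lighter-weight substitute for the frailty random
effect used in the original analysis, which is out of scope here. A nested
intercept-only fit supplies the likelihood-ratio statistic and AIC
difference, which satisfy `delta AIC = 2 * delta params - LR` exactly.
Survival curves follow `S(t|x) = 1 / (1 + (t / exp(x beta))^(1/sigma))`,
with `S(0) = 1` and `S = 0.5` exactly at the median `exp(x beta)`.

## What the synthetic data do and do not show

The generator reproduces the environment's stated physics and the
manipulations' information structure, and its scripted teams reproduce the
*directions* of the main empirical effects: informed and partitioned teams
finish faster and overlap less than fog-bound and shared-route teams,
18-target trials take longer than 9-target trials, and trials with more
persistent displacement structure finish faster (a negative AFT slope for
the DFA covariate). Passing these checks says the pipeline measures what
it claims to measure on data with known structure. It does **not** say the
scripted players are behaviorally equivalent to humans: absolute levels of
duration, overlap, and DFA exponents are properties of the scripts (for
example, scripted displacement-angle exponents sit well above the human
range because waypoint legs are straighter than human paths), there is no
learning across sessions, no verbal communication channel, and no
perceptual noise beyond the sensing radius. Human-level means from the
original study are therefore never used as quantitative targets.

## Problem sizes

The test suite runs the calibration at the full operating point (series of
length 1495, 50 seeds), the simulator contract on one full 300 s trial and
1,000 seeded spawns, oracle comparisons on 20 series and 10 polygon
fixtures, AFT recovery on 100 replicates of n = 500 (with a 400-replicate
null-calibration check at n = 120), and the direction suite on three cells
of 20 seeded trials each. The acceptance script reports the mean DFA
exponent of 50 antipersistent series of length 1495.
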