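---
title: "Weighted-constraint drift-diffusion modeling of maze planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-constraint drift-diffusion modeling of maze planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The task and the model

`mazeddm` analyzes initial path choices in grid-maze planning tasks in
which a mover must travel from a start cell, past two internal walls, to a
goal. Two factors jointly determine the shortest path: the *myopic
advantage* `mAdv` — the signed row offset of the start relative to the
center of the start-proximal wall — and the *future advantage* `fAdv` —
the offset of the goal (or, in the complex task, of the bottleneck opening
leading to the rest of the maze) relative to the goal-proximal wall. Each
unit of offset changes the length difference between the upper and lower
route candidates by two steps, so the two routes differ by
`2 * (mAdv + fAdv)` steps; this identity is enforced in the test suite by
an independent breadth-first-search oracle over every enumerated layout.

The first decision — move up or down — is modeled as a weighted constraint
satisfaction process implemented as a drift-diffusion model. A single
decision variable starts at `z`, accumulates with unit diffusion noise and
mean drift

    d = md * mAdv - fd * fAdv        (simple task)
    d = p * (md * mAdv - fd * fAdv) + gd * goal_sign   (subgoal condition)

and terminates at bounds `+a` (the choice satisfying the myopic advantage)
or `-a` (the choice satisfying the future advantage). Here `mAdv` and
`fAdv` enter as magnitudes in the myopic reference frame, `goal_sign` is
+1 when the final (initially irrelevant) goal lies on the side of the
myopic-satisfying move, `gd` is the weight that irrelevant goal carries,
and `p` is a shared proportional multiplier on both advantage weights in
the subgoal condition. The response time is the bound-hitting time plus a
non-decision time `t0`. Two sources of inter-trial variability complete
the model: the starting point is uniform with full range `sz` around `z`,
and the trial-level drift is Gaussian with SD `sd` around `d`.

All time-like parameters are expressed in standardized response-time
units: raw first-move times (seconds) are z-scored within participant
(sample-SD convention) and shifted so each participant's minimum is
exactly 0.5. Standardization happens after trial exclusions. `z` and `sz`
are absolute (not proportional to `a`); the diffusion coefficient is fixed
at 1 for identifiability, so the weights are in standardized-RT diffusion
units.

## Likelihood numerics

The first-passage-time density of the Wiener process between two absorbing
bounds is evaluated by the classical small-time and large-time series
expansions, switching by the standard per-series error bounds at a target
of 1e-7 per term set. Inter-trial variability is integrated by
Gauss-Hermite quadrature over the drift (31 nodes) and Gauss-Legendre
quadrature over the starting point (16 nodes); the unit tests verify these
against brute-force adaptive quadrature to well below the 1e-4 mass
tolerance, and verify conservation (the two defective densities integrate
to 1), the closed-form absorption probability in the variability-free
limit (to 1e-6), monotonicity in `d` and `z`, and agreement of the density
with an independent Euler-Maruyama forward simulation (step 1e-3) in both
choice fractions and Kolmogorov-Smirnov distance. Because discretely
monitored paths systematically overshoot a continuous barrier, the
simulator applies the standard Broadie-Glasserman-Kou continuity
correction (barriers pulled inward by `0.5826 * sqrt(dt)`), without which
the discretization bias is visible at 1e5 paths.

Densities at `rt <= t0`, and numerical underflow, are floored at 1e-10 so
the optimizer never sees `-Inf`. Degenerate inputs fail loudly: zero RT
variance in standardization, a start or goal inside a wall, an unreachable
goal, and action sequences leaving an unbounded grid all raise typed
errors rather than silently propagating.

A reduced quadrature (15 Hermite / 8 Legendre nodes) is available for
desk-scale cross-validation studies; the suite checks it reproduces the
default density to about 4e-4 absolute, far below the sNLL differences the
model comparison operates on.

## Trial construction

The canonical frame is 0-based `(row, col)`, left-to-right travel, up =
decreasing row, on an 11-row grid: start column 1, two length-7 walls in
columns 3 and 7 centered on row 5, goal column 9. Offsets are applied
along rows. Subgoal layouts extend the grid to 13 columns with a
bottleneck wall at column 10 (a single opening at the former goal
position) and the final goal in column 12 at either end of that column.
Exact cell coordinates are a free design choice; this parametric
geometry reproduces every designed advantage pairing and the
`2 * (mAdv + fAdv)` path-difference identity, and can be overridden via a
JSON config (`geometry_from_json()`).

The twelve designed advantage pairings (`advantage_table()`) are each
mirrored vertically except the neutral pairing, giving 23 signed layouts;
these expand over four orientations in the simple task (92 base trials)
and over the two orientations of one group in the complex task (46 base
trials, 92 subgoal trials including both goal ends). Mirroring negates
both advantage components; orientations are presentation metadata undone
by `canonicalize()`. Filler trials sample wall lengths (3/5/7), wall
shifts (uniform over positions that never block the boundary paths — the
sampling distributions are under-determined by those constraints, so
uniform was chosen and documented here), and start/goal cells; two
length-7 walls are never both centered, so no filler duplicates a designed
layout.

`path_length()` implements both collision rules: in the simple task a step
into a wall counts without moving; in the complex task (bounded canvas)
collisions neither move nor count.

## Preprocessing rules

Trials are excluded when the first move took over 60 s, when the executed
path is at least five steps longer than the longer of the two
route-constrained main candidates (steps counted under the experiment's
collision rule), or when the initial route is ill-identified: a first move
equivalent to going left in the canonical frame, or an initial vertical
move contradicting the side on which the path clears the start-proximal
wall. Reasons are assigned with that precedence, and the operation
partitions its input (kept + excluded = input; idempotent).

Participant accuracy is the proportion of optimal first moves over trials
with a unique optimal initial direction (pairs with `mAdv + fAdv = 0` have
two equally short routes and are excluded from the score); the probit
score is the inverse-normal transform capped at ±3, with proportions of 0
and 1 mapped directly to the caps. The median split assigns participants
strictly above the group median accuracy to the high group; ties at the
median go low, a deterministic policy. (With an odd cohort and no ties at
most `n - (n+1)/2` participants can strictly exceed the median, so
group sizes exceeding that bound would require ties to be broken upward;
the package keeps the strictly-above rule and documents it.)

## Fitting and model comparison

Candidate variants are fitted to the pooled incongruent-advantage trials
of all participants by bounded multi-start `nlminb` (numerical gradients)
minimizing the summed negative log-likelihood (sNLL). Bounds: `t0 ∈ [0,
0.45]` (below the 0.5 standardized-RT floor), `a ∈ (0.1, 5]`, weights in
`[0, 5]`, `sz ∈ [0, 4.9)` with the joint constraint `|z| + sz/2 < a`
enforced by a penalty, `sd ∈ [0, 3]`, `p ∈ (0.05, 3]`. After the initial
random starts, runs are extended in batches of five (capped, default 30)
until the best sNLL is replicated within 0.1 by a second run.

The simple-task lattice crosses equal vs different advantage weights,
fixed vs free starting bias, and absent vs present inter-trial
variabilities (eight variants). The complex-task lattice builds on the
different-weights-with-variabilities winner and varies the subgoal-trial
drift: no change; an added goal weight `gd`; `gd` plus a shared additive,
independent, or shared proportional (`p`) change to the advantage weights;
plus a separate-non-decision-time version of the proportional variant.

Monte-Carlo cross-validation holds out a random subset of participants per
fold (the full-scale protocol uses 200 folds with 35/95 held out in the
simple task and a 60/40 split in the complex task; the desk-scale default
is 20 folds). All variants share the same folds. Held-out sNLLs are
compared by fold-blocked paired t tests with Bonferroni adjustment — in
this balanced one-observation-per-variant-per-fold design the same
contrast structure as a fold-random-intercept linear mixed model, an
equivalence the test suite verifies against `lme4` directly. The winner is
the variant with reliably lowest held-out sNLL, or the variant with fewest
free parameters among those statistically indistinguishable from the
lowest.

## Individual differences

The winning variant is refitted separately to the high- and low-accuracy
groups. For the permutation baseline, participants are repeatedly
reassigned at random to two groups matched in size to the accuracy groups;
each random group is fitted on its full pooled data and the difference of
a parameter statistic (weight ratio `md/fd`, goal weight, or proportional
decrease `100*(1-p)`) is recorded. "More extreme" is one-sided (more
negative), matching how these baselines are reported, with a two-sided
option. The joint tail probability of independent split baselines is the
product of their tail proportions. Each split reuses a single
reduced-start fit per group — the full per-split fitting effort of the
original protocol is unstated, and the baseline distribution is driven by
the reassignment, not by optimizer jitter.

## The synthetic-data generator

Because no behavioral dataset ships with the package, every analysis stage
is validated on synthetic cohorts whose structure mirrors the designs:

* per-participant parameters are drawn from truncated normals centered on
  the winning fitted values. The simple-task population uses `t0 = 0.35`,
  `a = 1.2`, `md = 1.695`, `fd = 1.5` (ratio exactly 1.13), `sz = 0.3`,
  `sd = 0.8`: the target ratio pins down only the relative weights, so
  the remaining values were chosen once as typical of standardized-RT DDM
  fits of this kind, and are config-overridable. The complex-task
  population derives its base weights from the fitted subgoal-condition
  values (`md = 1.27/0.7`, `fd = 1.04/0.7`, `gd = 0.31`, `p = 0.7`).
* between-participant SDs (weights 0.15, `t0` 0.03, `a` 0.1, `sz` 0.05,
  `sd` 0.1, `gd` 0.06, `p` 0.02) represent modest heterogeneity — the
  fold-to-fold spread of pooled estimates says little about
  between-participant spread, so these were chosen once as realistic for
  a pooled-fitting design.
* choices and RTs come from the forward Euler-Maruyama simulation over the
  exact enumerated trial lists; action sequences are reconstructed as the
  shortest continuation consistent with the sampled route; artifacts that
  trigger each exclusion rule (timeouts, backward first moves, wandering
  paths) are planted at configurable rates and their counts must be
  reproduced exactly by the exclusion report.
* RTs are generated directly on the standardized scale (with `t0` below
  the 0.5 floor); an affine per-participant map to seconds exists so the
  standardization path can be tested end to end. Recovery fits consume the
  generator-scale RTs directly — re-standardizing simulated data would
  rescale the parameters per participant and break comparability.

What passing tests do and do not show: the generator realizes exactly the
model family the fits assume (up to heterogeneity pooled fits absorb into
`sz`/`sd` — visible as the upward `sz` bias in recovery reports). Real
data add contaminant processes (lapses, fast guesses, learning and fatigue
trends, non-stationary speed-accuracy trade-offs) that the generator does
not emulate, so parameter recovery here validates the estimation
machinery, not the model's adequacy for any particular dataset. Filler
trials and multi-subgoal trials are enumerated or excluded by design but
never simulated.

## Desk-scale study sizes

The validation studies are sized to run on a laptop:

* parameter recovery: 40 participants × the 48 simple-task (72
  complex-task) incongruent-advantage trials, pooled fits with 3-5 random
  starts. Recovered quantities of interest: the weight ratio (within ±0.1
  of the generating 1.13), the goal weight (±0.1) and the proportional
  decrease (±5 percentage points).
* model-selection recovery: 10 replicates × 20 shared folds per
  experiment, cohorts of 12 participants over the IA lists, the key
  competitor sets ({equal, different weights} and {baseline, +gd,
  +gd&proportional}), warm-started fold fits and the reduced quadrature.
  Generating effects are moderate by design — weight ratio 1.3 and goal
  weight 0.45 — because pilot power analyses showed that the fitted
  effect sizes themselves (ratio 1.13; goal weight 0.31) are too small
  for reliable 20-fold selection at desk-scale cohorts: with only a
  dozen participants, the per-fold held-out sNLL gap between the
  generating and the baseline structure is then comparable to its
  fold-to-fold variability, so the parsimony rule (correctly) falls back
  to the simpler model. Detecting effects that small requires full-scale
  cohorts. The generating structure must win (or lose only to a
  parsimony-equivalent) in at least 80% of replicates.
* the pipeline orchestrator (`run_pipeline()`) chains trial generation,
  simulation, preprocessing, cross-validated comparison and the group
  analysis with explicit per-stage seeds; identical configs produce
  byte-identical artifacts and a manifest of md5 hashes.

## Known limitations

* Pooled (fixed-effect) fitting, as in the original protocol — no
  hierarchical estimation of participant-level parameters.
* The likelihood assumes stationary parameters within participant and
  condition; collapsing bounds and attention-switching drift dynamics are
  out of scope.
* `sz` is mildly over-estimated under population heterogeneity (it absorbs
  between-participant variance), a known property of pooled DDM fits; the
  derived quantities used for validation (weight ratio, `gd`, `1 - p`) are
  robust to it.
* The probit cap at ±3 makes group averages insensitive to accuracy
  differences above ~99.9%.
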