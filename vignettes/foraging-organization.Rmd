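---
title: "Quantifying search organization in dynamic visual foraging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying search organization in dynamic visual foraging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a non-exhaustive visual foraging task an observer taps targets scattered
among distractors on a touch screen, is free to abandon the current display
("patch") at any moment, and — in the dynamic variant this package
addresses — every item drifts at a constant 44 px/s with pseudo-random
direction changes.  Displays hold 60, 100, 140 or 180 items on a
1400 x 1050 px screen, with 20–30% of them targets.  The scientific
questions are *how organized* the resulting scan-path is, how that
organization changes within a patch as targets are depleted, and how it
develops across ages.

`foragescan` implements the full analysis chain: four scan-path
organization indicators, a generative target-choice model with spatial and
strategy biases, two-bin time-course tables, and AIC-based comparison of
ten candidate mixed models — together with a simulator of the task, so the
whole chain is testable against known ground truth without any data
download.

## The organization indicators

All indicators are computed from the pick-time coordinates of the
*collected targets*, in collection order.  Distractor taps are retained in
trial logs but excluded from scoring, and every indicator reports `NA`
with a reason code (never a silent zero) when its minimum pick count is
not met.

**best-r** (`best_r`, needs 3 picks) correlates collection order with the
x coordinates and with the y coordinates and returns the larger absolute
Pearson correlation.  Reading-like sweeps score near 1; disorganized
searches score low.  A zero-variance axis contributes nothing (the other
axis alone supplies the value); if both are constant the score is
undefined.  Spiral searches are the indicator's documented blind spot —
organized, near-optimal, yet without a monotone axis component — and the
simulator's `spiral` agent exists to exhibit exactly that.

**mean ITD** (`mean_itd`, needs 2 picks) is the mean Euclidean distance
between consecutive picks, in pixels.  It shrinks with organization but
also mechanically with item density, which is why its set-size effects are
interpreted separately from the other indicators.

**PAO** (`pao`, needs 3 picks) is the percentage by which the realized
path exceeds the shortest open Hamiltonian path over the same points:
`(actual/optimal - 1) * 100`.  The optimum is found by
`optimal_open_path`:

* `n <= 10` (configurable): an exact Held–Karp dynamic program over
  subsets with free endpoints, `O(2^n n^2)`.  Tested against brute-force
  enumeration of all `n!` orders.
* larger `n`: nearest-neighbour construction from every start point, best
  tour refined by 2-opt reversals to a local optimum.

Because a heuristic optimum can in principle exceed the realized length
(the realized order is itself a Hamiltonian path, hence an upper bound on
the true optimum), the realized length replaces the heuristic value in
that case, so PAO is never negative and equals 0 exactly when the observed
order attains the computed optimum.  If all picks coincide the optimum is
0 and PAO is undefined (`degenerate_geometry`).

**Intersection rate** (`intersection_rate`, needs 4 picks) counts
unordered pairs of non-adjacent scan-path segments that cross, divided by
the number of picks.  Degenerate geometry is resolved deterministically
and documented, because real touch logs do hit these cases: a non-adjacent
segment passing exactly through another segment's endpoint counts once,
overlapping collinear non-adjacent segments count once, and orientation
tests use an epsilon of `1e-9` times the bounding-box scale.  The counter
is cross-checked in the test suite against an independently written
parametric-solver implementation on hundreds of random polylines,
including integer-lattice configurations where exact collinearity is
common.

All four indicators are invariant under rigid motions of the screen
coordinates (and best-r additionally under axis reflections and x/y swap),
so the top-left, y-down screen convention is immaterial; the tests assert
these invariances.

## The target-choice model

The choice model treats a trial as sequential sampling without
replacement: given the targets still on screen, the probability of picking
target `j` next is proportional to a product of four weights,

* class preference: `p_a` if `j` belongs to reference class A, else
  `1 - p_a`;
* class stickiness: `p_s` if `j` matches the previous pick's class, else
  `1 - p_s`;
* proximity: `exp(-rho_d * d_j / s)`, `d_j` the distance from the previous
  pick and `s` a fixed scale (default: the display diagonal, 1750 px);
* direction persistence: `exp(|rho_theta| * cos(dtheta_j - mu))`,
  `dtheta_j` the signed angle between the heading to `j` and the previous
  movement direction.

On the first pick only the class weight applies; on the second there is no
previous heading, so the direction weight is off.  With `p_a = p_s = 0.5`
and `rho_d = rho_theta = 0` the model is uniform over the remaining
targets, and with the spatial terms at zero it reduces exactly to the
two-parameter "bag" model of runs, switches and type preference.

Two conventions required decisions the task description leaves open:

* *Kernel forms.*  An exponential-decay distance kernel on distance
  standardized by the display diagonal, and a cosine (von-Mises-type)
  direction kernel.  Both are smooth, reduce to neutrality at zero, and
  make the parameters identifiable from realistic trial counts.
* *Sign of `rho_theta`.*  The magnitude is the persistence strength; the
  sign only routes the preferred direction offset `mu` (0 for positive
  values — straight-ahead persistence — and a lateral offset, default
  `-pi/2`, for negative values).  Only `|rho_theta|` is interpreted as
  strength, which `coef()` reports alongside the signed value.

### Estimation

`fit_bias()` maximizes the exact sequential likelihood by L-BFGS-B over
`(logit p_a, logit p_s, rho_d, rho_theta)` from a small multistart grid,
with `rho_d` bounded below by zero *on the raw scale*.  The raw scale was
chosen deliberately over `log(rho_d)`: the scientifically important null
hypothesis is neutrality, `rho_d = 0`, which is a boundary point on the
raw scale but `-Inf` on the log scale; raw-scale estimation makes
"within 2 standard errors of neutrality" a well-defined check and lets
truly neutral data estimate exactly 0.  Standard errors come from the
observed information at the optimum (delta-method transformed for `p_a`,
`p_s`).

A parameter whose covariate never varies *within* a choice step drops out
of the per-step normalization and is unidentifiable; `fit_bias` detects
this, pins the parameter at neutrality, flags it, and reports `NA`
standard errors.  The canonical case is the task-faithful display whose
targets all share one class: `p_a` and `p_s` are then meaningless, which
is why the display generator has a two-subtype option
(`n_target_classes = 2`) for choice-model studies.

The likelihood is evaluated against a static display snapshot per trial.
For simulated static trials it is exact; for moving displays it is an
approximation (item speed is small relative to inter-pick distances),
consistent with computing all indicators from pick-time coordinates.

Parameter recovery at the package's reference scale (200 trials of 15
picks on 100-item two-subtype displays) places `rho_d = 2` within a few
percent of truth and neutral data within 2 SE of neutrality on all four
parameters; recovery is monotone in the true value along a `rho_d` grid.
These checks run in the test suite.

## Time-course binning

`split_bins` divides each trial's target picks into the first and second
half (odd counts: extra pick to bin 1 — a fixed convention, since any
choice must be made and documented).  Bins are scored as self-contained
sequences: the travel between the last bin-1 pick and the first bin-2 pick
belongs to neither.  Trials whose bins fall below a configurable minimum
(default 4 picks, the smallest count at which all four indicators are
defined) are excluded with reason `"bin_too_small"` and reported in an
exclusion ledger, never silently dropped.  `build_score_table` assembles
the long participant x condition x set-size x bin table and adds
`log_age = ln(age)`, the age coding used by all candidate models (child
development is closer to logarithmic than linear in age).

## Candidate models and AIC comparison

`candidate_models()` defines ten fixed-effect structures over the four
predictors — all share the main effects of ln-age, condition, set size and
bin; they differ in interaction products (see the help page for the full
list).  Predictor coding is part of the model definition: `log_age` and
`set_size` numeric (set size is treated as linear), `condition` and `bin`
binary 0/1, interactions as elementwise products.  Under this coding the
parameter counts (fixed coefficients + random-intercept variance +
residual variance) are 7, 8, 8, 9, 8, 8, 9, 11, 12, 13 — note that the
largest model carries the age x set-size x condition three-way along with
the four-way product; that is the only composition consistent with its
published count of 13.  No centering is applied (it would change
coefficients, not likelihoods or AIC).

`fit_lmm_ml` fits each structure with `lme4` under full maximum likelihood
— not REML, because likelihoods from REML are not comparable across
different fixed-effect structures — with a single random intercept per
participant, observations being trial-bin rows.  Singular fits (zero
intercept variance) are retained and flagged.  `aic_table` reports AIC,
the small-sample corrected `AICc = AIC + 2k(k+1)/(n-k-1)`, and each
model's `delta` from the best AICc; exact ties go to the smaller model.
All ten fits must be computed on the identical row set, which
`fit_candidates` enforces by filtering missing responses once, up front.

## The simulator

The simulator exists so that every pipeline stage can be exercised against
known ground truth.  What it emulates, and the choices behind the parts
the task description leaves open:

* `gen_display`: uniform item positions, target fraction drawn uniformly
  in [0.20, 0.30], feature (four colors, one target color) or conjunction
  (two colors x two shapes, one target cell) class structure, headings
  uniform on `[0, 2pi)`.  A `ring` layout places items on an annulus for
  spiral-search studies.
* `step_motion`: constant 44 px/s, direction changes at exponentially
  distributed intervals (mean 1 s — memoryless and single-parameter, the
  natural reading of "pseudo-random intervals"), reflection at the display
  edges (keeps density uniform and items visible, unlike wrap-around).
  Distance traveled per step is exactly `44 * dt`, asserted in tests.
* `run_agent` interleaves choice and motion in the order the touch task
  imposes: the agent decides on current positions, then *pursues* the
  chosen target while everything keeps moving, and the recorded pick-time
  coordinates are those at the tap.  The search-plus-reach time per pick
  scales with target scarcity (`decision_interval * (n0/n_remaining)^slowdown`,
  default exponent 1): as the patch depletes, targets get harder to find
  while distractors remain, so time per target grows.  With a strongly
  proximity-driven agent this reproduces, as an emergent property, the
  headline time-course effect: mean ITD and PAO are both higher in the
  second half of a patch than in the first.
* Scanner and spiral agents plan a whole-display sweep once, at trial
  start: evenly spaced positions along the sweep axis (x, y, or angle
  around the centroid), nearest target to each, visited in sweep order.
  A naive "always take the leftmost remaining target" rule is not a
  scanner-like search under non-exhaustive quitting — it drains one edge
  of the screen and never sweeps — whereas the paced sweep reproduces the
  canonical regimes: scanner best-r >= 0.95 per trial on static displays,
  uniform-random best-r averaging well under 0.5, and spiral agents on
  ring displays scoring low best-r with near-zero PAO.
* `gen_lifespan_dataset` draws a cohort (ages uniform on 4–25 by default)
  whose proximity bias drifts linearly in ln(age)
  (`rho_d = max(0, intercept + slope * ln age + noise)`, defaults 0, 1 and
  SD 0.3 — placing children near `rho_d ~ 1.4` and adults near 3.2, a
  moderate, recoverable gradient), stickiness 0.6, neutral preference, and
  per-participant direction bias `N(0, 0.3)`.  Agents collect 60% of each
  display's targets by default (non-exhaustive).  The generating
  parameters are returned alongside the trial log and ready-to-fit
  `choice_data`, so recovery is testable end to end.

What the simulator does **not** emulate: distractor taps and their point
penalty (agents make no errors; the scoring economics and the 2 s travel
cost do not affect any indicator), motor/touch noise, fixation-level gaze
behavior, functional-visual-field limits, and patch-leaving economics —
agents quit by pick count or scarcity threshold, not by a marginal-value
rule.  Passing tests therefore demonstrate that the *pipeline* measures
what it claims on data with known structure, not that human data will show
any particular effect size.

## Numerical conventions and problem sizes

* Exact open-path solver up to 10 points (configurable); beyond that,
  NN + 2-opt with the PAO clamp.  2-opt uses a relative improvement
  threshold of `1e-12` times the largest pairwise distance.
* Intersection epsilon: `1e-9` x bounding-box scale; touch and collinear
  overlap conventions as above.
* Optimizer box: `|logit| <= 12`, `rho_d <= 60`, `|rho_theta| <= 50`;
  six multistarts spanning both direction-bias signs.
* The packaged checks use desk-scale problem sizes chosen to keep the
  whole suite around two minutes while leaving comfortable statistical
  margins: 200-replicate Monte-Carlo batches for regime separation and
  depletion, 200 trials x 15 picks for recovery, 100 replicates of the
  generator–selector loop at 279 simulated participants.

## Known limitations

* Heuristic PAO values on long trials depend on the heuristic and may
  differ slightly from other implementations' optima; the clamp guarantees
  only `PAO >= 0` and exactness below the DP threshold.
* The choice-model likelihood uses one display snapshot per trial;
  fitted spatial-bias magnitudes on moving displays inherit that
  approximation and are comparable across conditions rather than absolute.
* Whether to fit one parameter set per participant, per participant x
  condition, or pooled is a study design choice; the examples fit per
  participant x condition, which is the package default idiom
  (`gen_lifespan_dataset$choice_data` is keyed that way).
* AIC magnitudes from mixed models are data-set specific; only parameter
  counts, nesting relations, and delta orderings are structural claims.
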