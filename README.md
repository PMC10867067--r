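# foragescan

Tools for quantifying **search organization in dynamic, non-exhaustive
visual foraging**: tasks in which an observer taps targets among moving
distractors on a touch screen (items drift at 44 px/s on a 1400 x 1050 px
display of 60–180 items, 20–30% targets) and may abandon each display
("patch") at will.  The package is aimed at visual-cognition researchers
who need to score scan-paths, estimate choice biases, and model how
organization changes with age, condition, set size, and time within a
patch.

## What it computes

**Four scan-path organization indicators**, from the pick-time coordinates
of collected targets:

- **best-r** — `max(|r(order, x)|, |r(order, y)|)`, the stronger
  axis-wise Pearson correlation with collection order; near 1 for
  reading/scanner-like sweeps.
- **mean ITD** — mean Euclidean distance between consecutive picks (px).
- **PAO** — percentage above the optimal scan-path,
  `(L_actual / L_optimal − 1) × 100`, where `L_optimal` is the shortest
  *open* Hamiltonian path over the same points (exact dynamic program up
  to 10 picks, nearest-neighbour + 2-opt beyond, clamped so PAO ≥ 0).
- **intersection rate** — crossings between non-adjacent scan-path
  segments divided by the number of picks.

**A sampling-without-replacement choice model** with four bias
parameters, fit by maximum likelihood (`fit_bias`): class preference
`p_a`, class stickiness `p_s`, proximity `ρ_d` (weight
`exp(−ρ_d·d/s)`), and direction persistence `ρ_Θ` (weight
`exp(|ρ_Θ|·cos(Δθ − μ))`; only `|ρ_Θ|` is a strength, the sign encodes
the side of the bias).

**Time-course tables and model comparison**: each trial split into two
halves (`split_bins`, `build_score_table`), and ten candidate linear
mixed models (random participant intercept, ML) over ln-age, condition,
set size and bin compared by AIC/AICc/Δ (`fit_candidates`, `aic_table`).

**A task simulator** (`gen_display`, `step_motion`, `run_agent`,
`gen_lifespan_dataset`): moving displays, scanner / spiral / random /
choice-model forager agents, and lifespan-style cohorts with known
generating parameters — so the whole pipeline is testable with no data
download.

## Worked example

Score a scanner-like trial:

```r
library(foragescan)
set.seed(1)
pk <- run_agent(gen_display(140, "feature"),
                agent_policy("scanner_lr", n_picks = 12), motion = FALSE)
score_sequence(pk$x, pk$y)
#>     bin n_picks    best_r mean_itd      pao intersection_rate reasons
#> 1 whole      12 0.9984226 321.3784 5.312506                 0
```

A left-right sweep gives best-r ≈ 1 (order and x almost perfectly
correlated), a realized path only 5.3% longer than the shortest open path
through the same 12 points, and no self-crossings.

Recover choice biases from simulated foraging:

```r
set.seed(1)
truth <- bias_params(p_a = 0.6, p_s = 0.7, rho_d = 2, rho_theta = 0.5)
trials <- lapply(1:80, function(i) {
  d <- gen_display(100, "feature", n_target_classes = 2)
  list(display = d, picks = simulate_sequence(d, truth, 15)$id)
})
fit <- fit_bias(trials)
fit
#> Sampling-without-replacement choice model (maximum likelihood)
#>   80 trials, 1200 choices; logLik = -3203.65
#>   reference class A: blue.a; distance scale s = 1750.0 px
#>           p_a           p_s         rho_d     rho_theta abs_rho_theta
#>        0.6498        0.7103        1.5936        0.4895        0.4895
round(summary(fit), 3)
#>           estimate    se identifiable
#> p_a          0.650 0.030            1
#> p_s          0.710 0.014            1
#> rho_d        1.594 0.194            1
#> rho_theta    0.490 0.058            1
```

All four parameters land near their generating values with sensible
standard errors.  (`n_target_classes = 2` matters: with a single target
class, `p_a` and `p_s` cancel from every choice and are flagged
unidentifiable.)

Compare the ten candidate mixed models on a simulated cohort:

```r
set.seed(42)
cohort <- gen_lifespan_dataset(n_participants = 24, trials_per_condition = 6)
tab <- build_score_table(cohort$trials)
cmp <- aic_table(fit_candidates(tab$scores, "pao"))
cmp[cmp$best, c("model_id", "k", "logLik", "AICc", "delta")]
#>   model_id  k    logLik     AICc delta
#> 2        2  8 -2725.225 5466.713     0
```

`delta` is each model's AICc minus the best model's; the parameter counts
`k` for models 1–10 are 7, 8, 8, 9, 8, 8, 9, 11, 12, 13 under the
package's coding (ln-age and set size numeric, condition and bin binary).

## Package layout

- `R/org_metrics.R`, `R/tsp.R`, `R/intersections.R` — the four indicators
  and their geometry.
- `R/bias_model.R`, `R/bias_fit.R` — the choice model: weights,
  simulation, likelihood, ML fitting (`bias_fit` S3 class with `print`,
  `summary`, `coef`, `logLik`, `vcov`, `simulate` methods).
- `R/timecourse.R` — binning and the long score table.
- `R/model_selection.R` — candidate designs, ML mixed-model fits, AICc
  table.
- `R/synthetic.R`, `R/agents.R` — displays, motion, agents, cohorts.
- `R/trials.R`, `R/config.R` — trial-log CSV I/O, validation, YAML config.
- `vignettes/foraging-organization.Rmd` — the methods vignette: model
  definitions, conventions for degenerate geometry, estimation choices,
  and what the simulator does and does not emulate.
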