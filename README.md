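# lcasim

Monte-Carlo evaluation of latent class analysis (LCA) performance with
binary indicators: when do sample size, the number and quality of
indicators, and a covariate of class membership give trustworthy LCA
estimates, and when do they not?

Applied researchers fitting 2- or 3-class LCA models routinely face
questions like "is my N large enough?", "should I use all my indicators or
a subset?", and "does adding a covariate help or hurt?". `lcasim`
implements, as a tested and reusable pipeline, the full simulation
machinery needed to answer them: population specification over a factorial
design, data generation, maximum-likelihood estimation, replication
screening, and outcome metrics with effect-size summaries.

## The model

The unconditional LCA model for a binary response pattern
**y** = (y₁, …, y_J) is a finite mixture of Bernoulli products,

P(**Y** = **y**) = Σ_c γ_c Π_j π_{cj}^{y_j} (1 − π_{cj})^{1−y_j},

where γ_c is the proportion of latent class c and π_{cj} the conditional
response probability (CRP) of endorsing item j in class c, with items
locally independent given the class. With a covariate X the class
proportions become conditional through a multinomial logistic model,

P(L = c | X = x) = exp(β₀c + β₁c x) / Σ_k exp(β₀k + β₁k x),

with the last class as reference (β₀C = β₁C = 0), estimated in one step
jointly with the measurement model. Estimation is by EM (posterior
class-membership E step; weighted item means and a Newton-solved weighted
multinomial logistic regression in the M step), accelerated with monotone
squared-iteration extrapolation, using the convergence rule of at most 500
EM updates and an absolute log-likelihood change below 1e-7.

The simulated populations cross sample size (70–2000), number of
indicators (4–12), indicator quality (CRP pairs 0.7/0.3, 0.8/0.2,
0.9/0.1) and covariate effect size (odds ratios 1, 1.5, 2.5, 4) for
2-class (γ = 0.67/0.33) and 3-class (γ = 0.4/0.4/0.2) models — 1428
conditions. Each fitted replication passes an exclusion cascade
(zero-variance items, non-convergence, label switching detected from the
class assignment matrix, incorrigibility when no labeling reaches the
per-class accuracy floor); excluded replications are refilled three at a
time per missing replication, and any cell with fewer than 50% usable
initial replications is dropped outright.

## Worked example

Fit one replication of a well-behaved condition (2 classes, N = 500,
8 high-quality indicators, no covariate), then run the full cell at 100
replications:

```r
library(lcasim)

cell <- design_cell(2, 500, 8, "high", "none")
spec <- build_population_spec(cell)    # gamma = (0.67, 0.33), CRPs 0.9/0.1
d    <- generate_dataset(spec, 500, seed = 1)
fit  <- fit_lca(d, spec_to_params(spec))
fit
#> <lca fit: 2 classes, loglik -1640.5139, converged in 10 iterations, 0 boundary CRPs>
round(fit$estimate$gamma, 3)
#> [1] 0.69 0.31
round(crp_bias(fit, spec), 4)
#>   high    low
#> 0.0195 0.2351
```

The estimated class proportions (0.69/0.31) sit close to the generating
0.67/0.33, and the two high-CRP parameters are recovered to about 2%
relative bias; the two low CRPs (true value 0.1) show larger *relative*
bias (24%) because the same sampling error is divided by a smaller true
value.

```r
r <- run_cell(cell, target_reps = 100, root_seed = 42)
r$summary[, c("n_ok", "prop_nonconverged", "boundary_prevalence",
              "class1_bias", "high_crp_bias")]
#>  n_ok prop_nonconverged boundary_prevalence class1_bias high_crp_bias
#>   100                 0                   0  0.02911933    0.01505364
```

All 100 replications converge with correct labels, no CRP is estimated at
the 0/1 boundary, and the mean absolute relative bias of the Class-1
proportion is 2.9% — inside the under-10% region expected for moderate and
high quality conditions with at least 6 indicators and N ≥ 300.

## Analysis workflow

The numbered scripts under `analysis/` run the simulation pipeline at desk
scale: `01_design_grid.R` enumerates and exports the 1428-condition grid,
`02_pilot_simulation.R` runs a balanced 24-cell sub-grid at 50 usable
replications per cell, and `03_outcomes.R` computes the outcome table and
effect sizes (η² = SS_effect/SS_total for continuous outcomes, odds
ratios from logistic regression with ordinal factor scores for binary
outcomes). Results land under `results/`.

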