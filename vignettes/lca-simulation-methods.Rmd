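---
title: "Simulating the finite-sample performance of latent class analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the finite-sample performance of latent class analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcasim)
```

## The question and the model

Latent class analysis clusters individuals into C unobserved classes on
the basis of J binary indicators, assuming the indicators are independent
given the class. Its parameters are the class proportions γ_c and the
conditional response probabilities (CRPs) π_cj — the probability of
endorsing item j in class c. A continuous covariate X can be brought in
through a multinomial logistic model for class membership,
P(L = c | x) = softmax_c(β₀c + β₁c·x) with the last class as reference,
estimated in one step jointly with the measurement model.

`lcasim` studies, by Monte-Carlo simulation, how four design factors drive
the quality of maximum-likelihood estimation of correctly specified LCA
models: sample size, number of indicators, indicator quality, and the
strength of the covariate effect. The outcomes are the rates of
non-convergence and of solutions whose class labels cannot be trusted
(incorrigibility), the prevalence of boundary CRP estimates (probabilities
estimated at exactly 0 or 1), and the absolute relative bias of the
recovered parameters.

## Generating populations

Each design cell maps to a fully specified population:

* Class proportions: (0.67, 0.33) for 2 classes, (0.4, 0.4, 0.2) for 3,
  reflecting the common empirical situation of one class about twice the
  size of another.
* Class profiles: Class 1 endorses every item with the high CRP; Class 2
  with the high CRP on items 1, 2, 5, 7, 9, 11 (truncated to J) and the
  low CRP elsewhere; Class 3 (3-class models) with the low CRP
  everywhere. The extension of the "half high, half low" Class-2 profile
  to odd J follows the fixed 12-item assignment, so J = 5 gives Class 2
  three high and two low items.
* Quality levels map to CRP pairs: low (0.7, 0.3), moderate (0.8, 0.2),
  high (0.9, 0.1).
* Covariate levels map to slopes β₁c = log(OR) with OR ∈ {1, 1.5, 2.5, 4}
  (none / small / moderate / large, following odds-ratio effect-size
  conventions), equal across the non-reference classes. Intercepts are
  β₀c = log(γ_c/γ_C), so the class proportions *at the covariate mean*
  equal the unconditional proportions — the covariate is standard normal,
  so x = 0 is its mean. Responses are coded 0/1 and a CRP is
  P(response = 1 | class).

The grid crosses 7 sample sizes (70–2000), 9 indicator counts (4–12,
omitting 4 for 3-class models, which are underidentified there), 3 quality
levels and 4 covariate levels: 756 two-class plus 672 three-class
conditions. Sampling a replication draws x (if present), the class from
the logistic model (reducing to γ without a covariate), and the items as
independent Bernoulli draws given the class.

What the generator deliberately does *not* emulate: mixed indicator
quality within a model, polytomous or continuous indicators, multiple or
correlated covariates, and classes whose profiles depart from the
two-value CRP scheme. Results under the generator therefore speak to
designs resembling these populations, not to arbitrary real data.

## Estimation

The log-likelihood is maximized by EM. The E step computes posterior class
memberships; the M step sets each CRP to the posterior-weighted item mean
and, without a covariate, each γ_c to the mean posterior. With a
covariate, the structural coefficients maximize the posterior-weighted
multinomial logistic log-likelihood by Newton–Raphson with step halving
(gradient max-norm tolerance 1e-10, at most 50 inner iterations — the
inner problem is concave and 2(C−1)-dimensional, so this is cheap and
safe).

Starting values are the true population parameters, which shortens runs
and largely prevents label switching; random or user-supplied starts are
accepted for real-data use, but no multi-start search is attempted.

Convergence is declared when the absolute log-likelihood change falls
below 1e-7 within a budget of 500 EM updates. Plain EM converges
geometrically at a rate governed by the fraction of missing information;
in weakly separated conditions (few, low- or moderate-quality indicators)
that rate approaches 1 and plain EM can need thousands of iterations to
move the log-likelihood by less than 1e-7 — a probe of the 2-class,
5-indicator, moderate-quality, N = 1000 condition needed 1400–4600 plain
iterations, which the 500-update budget would misread as mass
non-convergence in cells where estimation is in fact unproblematic.
The fitter therefore accelerates EM with monotone squared-iteration
(SQUAREM-style) extrapolation: after two EM updates it attempts a step
along the squared difference of successive iterates, stabilizes the
extrapolated point with one further EM update, and accepts it only if the
log-likelihood does not decrease, falling back to the plain iterate
otherwise. Every accepted iterate is an EM image of a feasible point,
the reported trace is non-decreasing (asserted by tests at 1e-10 relative
tolerance), and the same stopping rule applies; the 500-update budget
counts every E+M map evaluation, including the stabilization steps.
The same probe converges in 16–94 updates under acceleration, to either
the identical optimum or an EM fixed point within ~0.03 log-likelihood
units on the flat ridge these weakly identified conditions exhibit.

Numerical choices worth recording:

* CRPs may hit exactly 0/1 during EM; logs are floored at 1e-300 so the
  vectorized likelihood stays NaN-free while zero-probability patterns
  still underflow to probability 0. A boundary estimate is any CRP within
  eps = 1e-4 of 0 or 1 — below substantive relevance, above round-off.
* A class whose total posterior mass falls below 1e-6·N is empirically
  degenerate; the fit is recorded as non-converged, mirroring how
  commercial ML software reports such estimation breakdowns as failures
  (their exact internal criteria are undocumented, so the mapping is a
  judgment call, recorded here).
* M-step weighted means are clamped to [0, 1] against floating-point
  overshoot.

## Screening replications

Each fitted replication passes a cascade, in precedence order:

1. **Zero variance** — any item with all-identical responses (a
   small-sample sampling accident) makes the replication unusable.
2. **Non-convergence** — budget exhausted or degenerate class.
3. **Labeling** — the class assignment matrix A cross-classifies true
   classes against modal posterior classes. The permutation maximizing
   the matched-class total is searched exhaustively (C ≤ 3). If it is not
   unique, or some class's matched accuracy falls below the accuracy
   floor, the replication is **incorrigible**: its recovery is too poor
   for any labeling to be trusted. Otherwise the labels are correct
   (identity) or **label-switched**; switched solutions are excluded
   rather than relabeled, since relabeling by inspection is exactly the
   subjective step the screening avoids. Ties in modal assignment break
   toward the lower class index.

The referenced screening idea fixes no numeric threshold, and whether
"assignment accuracy" is per-class or average is open; the per-class
minimum with floor 0.7 is used here (a class that captures under 70% of
its own members cannot anchor a labeling), exposed as a parameter so
sensitivity analyses can vary it.

## The harness

Each cell runs a fixed initial batch (1000 replications at full scale;
any smaller number runs the identical code path). If fewer than half of
the initial batch is usable the cell is excluded outright — such
conditions are infeasible in practice and refilling them would launder
them. Otherwise refill batches of three times the current shortfall are
generated with fresh seeds until the target count of usable replications
exists, so every included cell contributes a balanced count downstream.
A cap of 10 refill rounds guarantees termination and is recorded
separately ("refill_exhausted") from the 50% exclusion. The 50% rule is evaluated on
the initial batch only; refill batches cannot trigger exclusion.

Seeds derive deterministically from (root seed, cell index, replication
index), so refills never reuse streams and results are bit-identical
under any execution order or parallelism — asserted by tests comparing
result files byte for byte.

Non-convergence and incorrigibility are summarized over the initial batch
(before refilling); boundary prevalence and bias over the first
`target_reps` usable replications.

## Outcome metrics and effect sizes

Relative bias is |estimate − truth| / |truth|. CRP bias averages a fixed
pair of high-value and a fixed pair of low-value CRPs — the first two of
each in class-major order — keeping the metric comparable across models
with 4 to 12 indicators; boundary estimates are included, since applied
users would interpret them and low CRPs are sometimes estimated exactly
at zero. Class-proportion bias is per class; in covariate models the
intercepts β₀c play the class-proportion role (conditional proportions at
the covariate mean), and in 3-class models the two identically generated
slopes' biases are averaged. Boundary prevalence is the mean fraction of
the C·J CRPs flagged per usable replication.

Effect sizes over the design: η² = SS_effect/SS_total from the full
factorial fixed-effects decomposition for continuous outcomes (balance is
required and checked; the balanced decomposition is orthogonal, so the
term order is immaterial), and odds ratios from a logistic regression for
binary outcomes, each factor entered as one ordinal predictor rescaled to
[0, 1] so a single coefficient spans the factor's range. Replication-level
and cell-mean units of analysis are both supported, since η² can differ
between them; the analysis scripts use cell means for η² and
replication-level data for the odds ratios, mirroring how each outcome is
naturally recorded. Complete separation is flagged rather than silently
exponentiated.

## Problem sizes

The full 1428-cell × 1000-replication experiment is cluster-scale
(≈1.4 million fits) and runs through the same `run_grid()` interface. The
shipped analyses choose desk-scale sizes: the pilot sub-grid uses 24
cells × 50 usable replications (about a minute of CPU), the acceptance
checks use single 100,000-observation fits for large-sample recovery and
100–200 replications for per-cell rates. These sizes give Monte-Carlo
error comfortably inside the decision margins they are checked against
(e.g. a proportion estimated from 100 replications has standard error
below 5 percentage points).

## Known limitations

* Statuses beyond the iteration/tolerance rule (degenerate classes) are
  mapped to non-convergence; different ML implementations draw this line
  differently, so non-convergence rates in pathological cells are
  comparable across implementations only directionally.
* The accuracy floor 0.7 is a defensible but arbitrary point; the
  incorrigibility *ordering* across quality levels is robust to it, the
  absolute rates are not.
* No standard errors or model selection: simulation fits are correctly
  specified by construction, and boundary estimates make standard errors
  unavailable in exactly the interesting cells.
* Desk-scale effect sizes are directionally, not numerically, comparable
  to the full-scale experiment's.
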