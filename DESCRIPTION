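Package: lcasim
Title: Monte-Carlo Evaluation of Latent Class Analysis Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the finite-sample performance of latent class
    analysis (LCA) with binary indicators. Provides population specifications
    over a factorial design (sample size, number and quality of indicators,
    covariate effect size), a synthetic-data generator for Bernoulli-mixture
    populations with an optional standard-normal covariate acting on class
    membership through a multinomial logistic model, an EM maximum-likelihood
    estimator for unconditional and one-step covariate LCA models with
    boundary-estimate detection, replication diagnostics for label switching
    and incorrigibility, a simulation harness implementing replication refill
    and cell-exclusion policies, and outcome metrics (non-convergence,
    incorrigibility, boundary prevalence, absolute relative parameter bias)
    with eta-squared and odds-ratio effect-size summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr
Config/testthat/edition: 3
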