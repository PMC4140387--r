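# Shared fixtures: tiny populations and a brute-force log-likelihood used
# as an independent oracle for the EM machinery.

spec_2class <- function(J = 4, quality = "high", covariate = "none",
                        sample_size = 500) {
  build_population_spec(design_cell(2, sample_size, J, quality, covariate))
}

spec_3class <- function(J = 5, quality = "high", covariate = "none",
                        sample_size = 500) {
  build_population_spec(design_cell(3, sample_size, J, quality, covariate))
}

# A random, non-degenerate population spec for property-style tests.
random_spec <- function(C = sample(2:3, 1), J = sample(3:6, 1)) {
  gamma <- as.numeric(stats::rgamma(C, 2) + 0.2)
  gamma <- gamma / sum(gamma)
  crp <- matrix(stats::runif(C * J, 0.05, 0.95), C, J)
  population_spec(gamma, crp)
}

# Brute-force observed-data log-likelihood: sums, per observation, the log
# of the directly enumerated mixture probability of its response pattern.
# Independent of the estimator's vectorized path.
brute_loglik <- function(params, d) {
  y <- d$responses
  prior <- if (params$has_covariate) NULL else params$gamma
  total <- 0
  for (i in seq_len(nrow(y))) {
    if (params$has_covariate)
      prior <- softmax(params$beta0 + params$beta1 * d$x[i])
    p_i <- 0
    for (c in seq_len(params$n_classes)) {
      lik <- prod(ifelse(y[i, ] == 1, params$crp[c, ], 1 - params$crp[c, ]))
      p_i <- p_i + prior[c] * lik
    }
    total <- total + log(p_i)
  }
  total
}
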