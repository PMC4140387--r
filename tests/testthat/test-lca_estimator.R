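test_that("log-likelihood matches brute-force enumeration and mixture symmetry", {
  # single class collapses to independent Bernoulli items
  s1 <- population_spec(1, matrix(c(0.3, 0.8), 1, 2))
  d1 <- generate_dataset(s1, 100, seed = 1)
  p <- s1$crp[1, ]
  manual <- sum(d1$responses %*% log(p) + (1 - d1$responses) %*% log(1 - p))
  expect_equal(lca_loglikelihood(spec_to_params(s1), d1), manual)

  set.seed(11)
  for (i in 1:8) {
    s <- random_spec()
    d <- generate_dataset(s, 60, seed = 1000 + i)
    params <- spec_to_params(s)
    expect_equal(lca_loglikelihood(params, d), brute_loglik(params, d),
                 tolerance = 1e-10)
    # label permutation leaves the mixture density unchanged
    perm <- sample(s$n_classes)
    permuted <- parameter_set(params$crp[perm, , drop = FALSE],
                              gamma = params$gamma[perm])
    expect_equal(lca_loglikelihood(permuted, d),
                 lca_loglikelihood(params, d), tolerance = 1e-12)
  }
})

test_that("posterior class probabilities follow Bayes' rule", {
  # uninformative items: posterior equals the prior
  s <- population_spec(c(0.25, 0.75), matrix(0.6, 2, 3))
  d <- generate_dataset(s, 20, seed = 2)
  post <- e_step(spec_to_params(s), d)
  expect_equal(post, matrix(c(0.25, 0.75), 20, 2, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)

  # deterministic single indicator pins the class
  pd <- parameter_set(rbind(1 - 1e-12, 1e-12), gamma = c(0.5, 0.5))
  dd <- structure(list(responses = matrix(1L, 1, 1), x = NULL,
                       true_class = 1L, seed = 0L), class = "lca_dataset")
  expect_equal(e_step(pd, dd)[1, ], c(1, 0), tolerance = 1e-9)

  # hand-normalized two-term mixture for one observation
  s4 <- spec_2class(J = 4, quality = "high")
  dy <- structure(list(responses = matrix(c(1L, 1L, 0L, 0L), 1, 4), x = NULL,
                       true_class = 1L, seed = 0L), class = "lca_dataset")
  t1 <- 0.67 * 0.9 * 0.9 * 0.1 * 0.1
  t2 <- 0.33 * 0.9 * 0.9 * 0.9 * 0.9
  expect_equal(unname(e_step(spec_to_params(s4), dy)[1, ]),
               c(t1, t2) / (t1 + t2), tolerance = 1e-12)
})

test_that("M step recovers complete-data maximum likelihood under hard weights", {
  s <- spec_2class(J = 5, quality = "moderate")
  d <- generate_dataset(s, 400, seed = 3)
  hard <- cbind(d$true_class == 1, d$true_class == 2) * 1
  est <- m_step(hard, d)
  for (c in 1:2) {
    expect_equal(unname(est$crp[c, ]),
                 unname(colMeans(d$responses[d$true_class == c, ])))
  }
  expect_equal(est$gamma, unname(colMeans(hard)))

  # all posterior mass on one class trips the degenerate-class signal
  one <- cbind(rep(1, 400), rep(0, 400))
  expect_error(m_step(one, d), class = "lca_degenerate_class")
})

test_that("weighted multinomial logit matches closed forms and an independent fit", {
  s <- spec_2class(J = 6, quality = "high", covariate = "moderate")
  d <- generate_dataset(s, 2000, seed = 4)
  w <- cbind(d$true_class == 1, d$true_class == 2) * 1

  # intercept-only solution is the closed-form logit of the mean weights
  io <- weighted_multilogit(w, d$x, intercept_only = TRUE)
  expect_equal(io$beta0, proportions_to_intercepts(colMeans(w)),
               tolerance = 1e-8)
  expect_true(io$converged)

  # against stats::glm on the hard labels (class 1 vs reference class 2)
  full <- weighted_multilogit(w, d$x)
  g <- stats::glm(w[, 1] ~ d$x, family = stats::binomial())
  expect_equal(full$beta0[1], unname(stats::coef(g)[1]), tolerance = 1e-6)
  expect_equal(full$beta1[1], unname(stats::coef(g)[2]), tolerance = 1e-6)

  # 3-class case against nnet::multinom with class 3 as reference
  skip_if_not_installed("nnet")
  s3 <- spec_3class(J = 6, covariate = "large")
  d3 <- generate_dataset(s3, 3000, seed = 5)
  w3 <- outer(d3$true_class, 1:3, "==") * 1
  full3 <- weighted_multilogit(w3, d3$x)
  cls <- factor(d3$true_class, levels = c(3, 1, 2))
  m <- suppressMessages(nnet::multinom(cls ~ d3$x, trace = FALSE, reltol = 1e-14))
  cf <- stats::coef(m) # rows: class 1 and class 2 vs reference 3
  expect_equal(full3$beta0[1:2], unname(cf[, 1]), tolerance = 1e-4)
  expect_equal(full3$beta1[1:2], unname(cf[, 2]), tolerance = 1e-4)
})

test_that("EM increases the log-likelihood monotonically and converges", {
  set.seed(21)
  for (i in 1:6) {
    s <- random_spec()
    d <- generate_dataset(s, 150, seed = 2000 + i)
    if (zero_variance_check(d)$any) next
    fit <- fit_lca(d, spec_to_params(s))
    tr <- fit$loglik_trace
    expect_gte(min(diff(tr)), -1e-10 * max(abs(tr)))
    if (fit$converged)
      expect_lt(abs(tr[length(tr)] - tr[length(tr) - 1]), 1e-7)
  }
})

test_that("EM restarted at its own solution is a fixed point", {
  s <- spec_2class(J = 6, quality = "moderate")
  d <- generate_dataset(s, 500, seed = 6)
  fit <- fit_lca(d, spec_to_params(s))
  expect_true(fit$converged)
  refit <- fit_lca(d, fit$estimate)
  expect_true(refit$converged)
  expect_lte(refit$n_iterations, 2)
  expect_equal(refit$estimate$crp, fit$estimate$crp, tolerance = 1e-4)
})

test_that("fitting from a permuted start yields the permuted solution", {
  s <- spec_2class(J = 6, quality = "moderate")
  d <- generate_dataset(s, 500, seed = 7)
  start <- spec_to_params(s)
  fit <- fit_lca(d, start)
  swapped <- parameter_set(start$crp[2:1, ], gamma = start$gamma[2:1])
  fit2 <- fit_lca(d, swapped)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
  expect_equal(fit2$estimate$crp, fit$estimate$crp[2:1, ], tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("large-sample EM recovers the generating parameters", {
  s <- spec_2class(J = 8, quality = "high")
  d <- generate_dataset(s, 100000, seed = 8)
  fit <- fit_lca(d, spec_to_params(s))
  expect_true(fit$converged)
  se_gamma <- sqrt(0.67 * 0.33 / 100000)
  expect_lt(abs(fit$estimate$gamma[1] - 0.67), 3 * se_gamma)
  high_idx <- abs(s$crp - 0.9) < 1e-12
  # binomial error of a class-conditional item mean, smallest class share
  se_crp <- sqrt(0.9 * 0.1 / (0.33 * 100000))
  expect_lt(max(abs(fit$estimate$crp[high_idx] - 0.9)), 3 * se_crp)
})

test_that("repeated moderate-sample fits keep mean CRP bias small", {
  s <- spec_2class(J = 8, quality = "high", sample_size = 2000)
  start <- spec_to_params(s)
  bias <- vapply(1:100, function(i) {
    d <- generate_dataset(s, 2000, seed = 30000 + i)
    fit <- fit_lca(d, start)
    mean(relative_bias(fit$estimate$crp, s$crp))
  }, numeric(1))
  expect_lt(mean(bias), 0.05)
})

test_that("boundary CRP estimates are flagged at the 0/1 edge", {
  p <- parameter_set(rbind(c(1, 0.5, 1e-5, 0.3), c(0, 0.99995, 0.7, 0.2)),
                     gamma = c(0.5, 0.5))
  bd <- detect_boundary(p, eps = 1e-4)
  expect_identical(unname(bd$mask),
                   rbind(c(TRUE, FALSE, TRUE, FALSE),
                         c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(bd$count, 4)
  all_bd <- parameter_set(matrix(rep(c(0, 1), 4), 2, 4), gamma = c(0.5, 0.5))
  expect_equal(detect_boundary(all_bd)$count, 8)
})
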