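test_that("relative bias follows its definition and rejects a zero truth", {
  expect_equal(relative_bias(0.5, 0.5), 0)
  expect_equal(relative_bias(0.6, 0.5), 0.2)
  expect_equal(relative_bias(0.4, 0.5), 0.2)
  # equal raw error, different true values: smaller truth inflates the ratio
  expect_equal(relative_bias(0.05, 0.1), 0.5)
  expect_equal(relative_bias(0.85, 0.9), 0.05 / 0.9)
  expect_error(relative_bias(0.1, 0), "undefined")
})

test_that("CRP bias averages a fixed pair of high and low parameters", {
  s <- spec_2class(J = 4, quality = "high")
  exact <- spec_to_params(s)
  expect_equal(crp_bias(exact, s), c(high = 0, low = 0))

  # low CRPs estimated at exactly zero: relative bias 1
  est <- exact
  est$crp[abs(est$crp - 0.1) < 1e-12] <- 0
  expect_equal(crp_bias(est, s)[["low"]], 1)

  # hand-built estimate vs spreadsheet-style recomputation:
  # high pair = class 1 items 1-2 (truth 0.9); low pair = class 2 items 3-4
  est2 <- parameter_set(rbind(c(0.95, 0.85, 0.9, 0.9), c(0.9, 0.9, 0.2, 0.05)),
                        gamma = c(0.67, 0.33))
  expect_equal(crp_bias(est2, s)[["high"]],
               mean(c(abs(0.95 - 0.9), abs(0.85 - 0.9)) / 0.9))
  expect_equal(crp_bias(est2, s)[["low"]],
               mean(c(abs(0.2 - 0.1), abs(0.05 - 0.1)) / 0.1))
})

test_that("structural bias covers proportions, intercepts, and averaged slopes", {
  s <- spec_2class(J = 4)
  exact <- spec_to_params(s)
  out <- structural_bias(exact, s)
  expect_equal(unname(out$class), c(0, 0))
  expect_true(is.na(out$slope))

  est <- parameter_set(s$crp, gamma = c(0.70, 0.30))
  out2 <- structural_bias(est, s)
  expect_equal(unname(out2$class), c(0.03 / 0.67, 0.03 / 0.33))

  # 3-class covariate model: both slopes generated at log(2.5), bias averaged
  s3 <- spec_3class(J = 6, covariate = "moderate")
  est3 <- parameter_set(s3$crp, beta0 = s3$beta0, beta1 = c(0.9, 1.0, 0))
  out3 <- structural_bias(est3, s3)
  truth <- log(2.5)
  expect_equal(out3$slope,
               mean(c(abs(0.9 - truth), abs(1.0 - truth)) / truth))
  expect_equal(length(out3$class), 2) # reference intercept carries no bias
})

test_that("boundary prevalence is the mean flagged fraction", {
  expect_equal(boundary_prevalence(c(0, 0, 0), 16), 0)
  expect_equal(boundary_prevalence(c(16, 16), 16), 1)
  expect_equal(boundary_prevalence(c(0, 4, 8), 16), 0.25)
  expect_true(is.na(boundary_prevalence(integer(0), 16)))
})

test_that("eta squared equals its closed forms on a balanced layout", {
  # constant outcome: defined as zero
  df0 <- expand.grid(quality = c("low", "high"), covariate = c("none", "large"))
  df0$y <- 1
  expect_equal(eta_squared(df0, "y", "quality"), 0)

  # single two-level factor: eta squared = squared point-biserial correlation
  set.seed(61)
  df1 <- data.frame(quality = rep(c("low", "high"), each = 30))
  df1$y <- stats::rnorm(60) + (df1$quality == "high") * 0.8
  e <- eta_squared(df1, "y", "quality", factors = "quality")
  expect_equal(e, stats::cor(df1$y, df1$quality == "high")^2, tolerance = 1e-10)

  # orthogonal decomposition: effects plus residual exhaust the total SS
  set.seed(62)
  df2 <- expand.grid(quality = c("low", "moderate", "high"),
                     covariate = c("none", "small", "moderate", "large"),
                     rep = 1:5)
  df2$y <- stats::rnorm(nrow(df2)) + as.integer(factor(df2$quality)) * 0.5
  terms <- c("quality", "covariate", "quality:covariate")
  parts <- vapply(terms, function(t)
    eta_squared(df2, "y", t, factors = c("quality", "covariate")), numeric(1))
  resid_ss <- stats::anova(stats::aov(y ~ quality * covariate, df2))["Residuals", "Sum Sq"]
  expect_equal(sum(parts) + resid_ss / sum((df2$y - mean(df2$y))^2), 1,
               tolerance = 1e-10)
  # term order does not matter
  expect_equal(eta_squared(df2, "y", "covariate:quality",
                           factors = c("quality", "covariate")),
               parts[["quality:covariate"]])

  # unbalanced input is rejected
  df3 <- df2[-1, ]
  expect_error(eta_squared(df3, "y", "quality",
                           factors = c("quality", "covariate")), "unbalanced")
})

test_that("odds-ratio effects recover known logistic slopes and flag separation", {
  set.seed(63)
  n <- 4000
  df <- data.frame(quality = sample(c("low", "moderate", "high"), n, TRUE))
  z <- (match(df$quality, c("low", "moderate", "high")) - 1) / 2
  df$quality <- factor(df$quality, levels = c("low", "moderate", "high"))

  # null: outcome independent of the factor
  df$y0 <- stats::rbinom(n, 1, 0.3)
  out0 <- or_effect(df, "y0", "quality", factors = "quality")
  expect_false(out0$separated)
  expect_lt(abs(log(out0$or)), 0.25)

  # known slope 1 on the rescaled score: OR converges to e
  df$y1 <- stats::rbinom(n, 1, stats::plogis(-0.5 + 1 * z))
  out1 <- or_effect(df, "y1", "quality", factors = "quality")
  expect_equal(log(out1$or), 1, tolerance = 0.25)

  # perfectly determined outcome: separation flagged
  df$y2 <- as.integer(z > 0.4)
  out2 <- or_effect(df, "y2", "quality", factors = "quality")
  expect_true(out2$separated)
})

test_that("ordinal rescaling keeps the design's weak-to-strong level order", {
  # plain character columns (e.g. read back from CSV) must not be sorted
  # alphabetically: low < moderate < high, none < small < moderate < large
  set.seed(65)
  df <- expand.grid(quality = c("low", "moderate", "high"), rep = 1:300,
                    stringsAsFactors = FALSE)[, "quality", drop = FALSE]
  p <- c(low = 0.6, moderate = 0.3, high = 0.1)[df$quality]
  df$y <- stats::rbinom(nrow(df), 1, p)
  out <- or_effect(df, "y", "quality", factors = "quality")
  expect_lt(out$or, 1) # raising quality reduces the outcome rate
})

test_that("cell outcomes are invariant to replication order", {
  r <- run_cell(design_cell(2, 200, 8, "high", "none"),
                target_reps = 20, root_seed = 64)
  rec <- r$records
  shuffled <- rec[sample(nrow(rec)), ]
  ok <- rec$status == "ok"
  expect_equal(mean(shuffled$high_crp_bias[shuffled$status == "ok"]),
               mean(rec$high_crp_bias[ok]))
  expect_equal(boundary_prevalence(shuffled$boundary_count[shuffled$status == "ok"], 16),
               boundary_prevalence(rec$boundary_count[ok], 16))
})
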