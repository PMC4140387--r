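# Maximum-likelihood estimation of latent class models for binary items by
# expectation-maximization. The measurement model is a finite mixture of
# Bernoulli products (local independence given class); the structural model
# is either a free class-proportion vector or, in one-step covariate models,
# a multinomial logistic regression of class membership on a single
# continuous covariate, maximized jointly with the item parameters.

# Row-wise max of a matrix without apply(); C is small, N may be large.
.row_max <- function(m) {
  r <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) r <- pmax(r, m[, j])
  r
}

# Row-wise log-sum-exp.
.row_lse <- function(m) {
  mx <- .row_max(m)
  s <- exp(m[, 1] - mx)
  for (j in seq_len(ncol(m))[-1]) s <- s + exp(m[, j] - mx)
  out <- mx + log(s)
  out[mx == -Inf] <- -Inf
  out
}

# Floor used inside log() so that CRPs estimated exactly at 0 or 1 do not
# produce NaN in the vectorized likelihood; exp(log(.crp_floor)) underflows
# to 0, preserving the probability semantics.
.crp_floor <- 1e-300

#' Construct a parameter set
#'
#' The parameters of an LCA model: the C x J matrix of conditional
#' response probabilities plus either unconditional class proportions or
#' multinomial-logit coefficients (intercepts and covariate slopes, the
#' last class as reference). Unlike a population specification, CRPs may
#' sit exactly at the 0/1 boundary.
#'
#' @param crp C x J matrix of response probabilities in \[0, 1\].
#' @param gamma Class proportions (unconditional model) or `NULL`.
#' @param beta0,beta1 Logit intercepts and slopes of length C with last
#'   entry 0 (covariate model), or `NULL`.
#' @return An object of class `lca_params`.
#' @export
parameter_set <- function(crp, gamma = NULL, beta0 = NULL, beta1 = NULL) {
  crp <- as.matrix(crp)
  C <- nrow(crp)
  if (any(crp < 0 | crp > 1))
    stop("CRPs must lie in [0, 1]")
  has_covariate <- !is.null(beta1)
  if (has_covariate) {
    if (is.null(beta0) || length(beta0) != C || length(beta1) != C)
      stop("beta0 and beta1 must both have length C")
    if (beta0[C] != 0 || beta1[C] != 0)
      stop("reference-class (last) coefficients must be 0")
    gamma <- softmax(beta0) # proportions at the covariate mean
  } else {
    if (is.null(gamma) || length(gamma) != C)
      stop("gamma must have length C")
    if (abs(sum(gamma) - 1) > 1e-8 || any(gamma < 0))
      stop("gamma must be a probability vector")
    beta0 <- beta1 <- NULL
  }
  structure(
    list(crp = crp, gamma = as.numeric(gamma),
         beta0 = if (has_covariate) as.numeric(beta0) else NULL,
         beta1 = if (has_covariate) as.numeric(beta1) else NULL,
         n_classes = C, n_indicators = ncol(crp),
         has_covariate = has_covariate),
    class = "lca_params"
  )
}

#' Parameter set holding a population's true values
#'
#' Converts an `lca_pop_spec` into the `lca_params` layout, e.g. for use
#' as true-parameter starting values.
#'
#' @param spec An `lca_pop_spec`.
#' @return An `lca_params`.
#' @export
spec_to_params <- function(spec) {
  stopifnot(inherits(spec, "lca_pop_spec"))
  if (spec$has_covariate) {
    parameter_set(spec$crp, beta0 = spec$beta0, beta1 = spec$beta1)
  } else {
    parameter_set(spec$crp, gamma = spec$class_proportions)
  }
}

# N x C matrix of log P(y_i | class c) under local independence.
.class_logdensity <- function(params, y) {
  lp <- log(pmax(params$crp, .crp_floor))
  lq <- log(pmax(1 - params$crp, .crp_floor))
  y %*% t(lp) + (1 - y) %*% t(lq)
}

# N x C matrix of log prior class probabilities (rows identical without a
# covariate).
.class_logprior <- function(params, x, n) {
  if (params$has_covariate) {
    if (is.null(x)) stop("covariate model requires a covariate column")
    eta <- outer(x, params$beta1) + rep(params$beta0, each = n)
    eta - .row_lse(eta)
  } else {
    matrix(log(params$gamma), nrow = n, ncol = params$n_classes, byrow = TRUE)
  }
}

#' Log-likelihood of a parameter set on a dataset
#'
#' The observed-data log-likelihood: the sum over observations of the log
#' mixture density. Observations whose pattern has probability 0 under the
#' parameters contribute `-Inf`, which is returned rather than raised.
#'
#' @param params An `lca_params`.
#' @param d An `lca_dataset`.
#' @return A single numeric (possibly `-Inf`).
#' @export
lca_loglikelihood <- function(params, d) {
  y <- d$responses
  n <- nrow(y)
  ll <- .class_logdensity(params, y) + .class_logprior(params, d$x, n)
  sum(.row_lse(ll))
}

#' E step: posterior class-membership probabilities
#'
#' `posterior[i, c]` is proportional to the class prior (conditional on
#' the covariate when present) times the class-conditional response
#' density; rows are normalized to sum to 1.
#'
#' @param params An `lca_params`.
#' @param d An `lca_dataset`.
#' @return An N x C matrix with rows summing to 1.
#' @export
e_step <- function(params, d) {
  y <- d$responses
  n <- nrow(y)
  ll <- .class_logdensity(params, y) + .class_logprior(params, d$x, n)
  m <- .row_max(ll)
  bad <- which(m == -Inf)
  if (length(bad))
    stop("observation ", bad[1],
         " has zero probability under every class; posterior undefined")
  w <- exp(ll - m)
  w / rowSums(w)
}

#' M step: parameter update from posterior weights
#'
#' CRPs are posterior-weighted item means per class. Without a covariate
#' the class proportions are the mean posterior per class; with a
#' covariate the logit coefficients maximize the posterior-weighted
#' multinomial logistic log-likelihood via Newton-Raphson.
#'
#' @param posterior N x C matrix of weights with rows summing to 1.
#' @param d An `lca_dataset`.
#' @param has_covariate Fit the logistic structural model on `d$x`.
#' @param class_floor Minimum total posterior mass per class, as a
#'   fraction of N; below it the class is empirically degenerate and a
#'   condition-of-class error is raised (mapped to non-convergence by the
#'   caller).
#' @return An `lca_params`.
#' @export
m_step <- function(posterior, d, has_covariate = FALSE, class_floor = 1e-6) {
  y <- d$responses
  n <- nrow(y)
  mass <- colSums(posterior)
  if (any(mass < class_floor * n)) {
    cls <- which.min(mass)
    stop(structure(
      class = c("lca_degenerate_class", "error", "condition"),
      list(message = sprintf("class %d retains negligible posterior mass (%.3g)",
                             cls, mass[cls]),
           call = sys.call())
    ))
  }
  crp <- t(posterior) %*% y / mass
  crp <- pmin(pmax(crp, 0), 1) # guard floating-point overshoot at the boundary
  if (has_covariate) {
    fit <- weighted_multilogit(posterior, d$x)
    parameter_set(crp, beta0 = fit$beta0, beta1 = fit$beta1)
  } else {
    parameter_set(crp, gamma = mass / n)
  }
}

#' Posterior-weighted multinomial logistic regression
#'
#' Maximizes `sum_i sum_c w_ic log softmax_c(beta0 + beta1 x_i)` over the
#' 2(C-1) free coefficients (last class fixed at 0) by Newton-Raphson with
#' step halving. The problem is concave; convergence is declared on the
#' gradient max-norm.
#'
#' @param w N x C weight matrix with rows summing to 1.
#' @param x Numeric covariate of length N.
#' @param intercept_only Fix all slopes at 0 and estimate intercepts only
#'   (closed-form check: intercepts then equal
#'   `proportions_to_intercepts(colMeans(w))`).
#' @param tol Gradient max-norm tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return A list with `beta0`, `beta1` (length C, last entry 0),
#'   `converged` and `n_iter`.
#' @export
weighted_multilogit <- function(w, x, intercept_only = FALSE,
                                tol = 1e-10, max_iter = 50) {
  n <- nrow(w)
  C <- ncol(w)
  K <- C - 1L
  X <- if (intercept_only) cbind(rep(1, n)) else cbind(1, x) # n x p
  p <- ncol(X)
  theta <- matrix(0, nrow = p, ncol = K) # coefficients per non-reference class

  obj <- function(theta) {
    eta <- cbind(X %*% theta, 0)
    sum(w * eta) - sum(.row_lse(eta))
  }
  probs <- function(theta) {
    eta <- cbind(X %*% theta, 0)
    e <- exp(eta - .row_max(eta))
    e / rowSums(e)
  }

  ll <- obj(theta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    P <- probs(theta)
    R <- w[, seq_len(K), drop = FALSE] - P[, seq_len(K), drop = FALSE]
    grad <- as.numeric(crossprod(X, R)) # p*K vector, class-major blocks
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    H <- matrix(0, p * K, p * K)
    for (a in seq_len(K)) for (b in seq_len(K)) {
      v <- if (a == b) P[, a] * (1 - P[, a]) else -P[, a] * P[, b]
      H[((a - 1) * p + 1):(a * p), ((b - 1) * p + 1):(b * p)] <-
        crossprod(X, X * v)
    }
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step))
      stop("singular Hessian in the weighted logistic M step")
    # Newton ascent with step halving to guarantee monotone inner updates
    lambda <- 1
    repeat {
      cand <- theta + matrix(lambda * step, nrow = p)
      ll_new <- obj(cand)
      if (ll_new >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    theta <- cand
    ll <- ll_new
  }
  beta0 <- c(theta[1, ], 0)
  beta1 <- if (intercept_only) rep(0, C) else c(theta[2, ], 0)
  list(beta0 = beta0, beta1 = beta1, converged = converged, n_iter = iter)
}

# Pack the free parameters into a vector for extrapolation, and unpack
# with projection back into the feasible region (CRPs clamped to [0, 1],
# proportions renormalized; logit coefficients are unconstrained).
.pack_params <- function(params) {
  if (params$has_covariate) {
    C <- params$n_classes
    c(as.numeric(params$crp), params$beta0[-C], params$beta1[-C])
  } else {
    c(as.numeric(params$crp), params$gamma)
  }
}

.unpack_params <- function(theta, template) {
  C <- template$n_classes
  J <- template$n_indicators
  crp <- matrix(pmin(pmax(theta[seq_len(C * J)], 0), 1), C, J,
                dimnames = dimnames(template$crp))
  rest <- theta[-seq_len(C * J)]
  if (template$has_covariate) {
    K <- C - 1L
    parameter_set(crp, beta0 = c(rest[seq_len(K)], 0),
                  beta1 = c(rest[K + seq_len(K)], 0))
  } else {
    g <- pmax(rest, 1e-12)
    parameter_set(crp, gamma = g / sum(g))
  }
}

#' Fit an LCA model by EM
#'
#' Alternates [e_step()] and [m_step()] from the supplied start until the
#' absolute change in log-likelihood falls below `tol` or `max_iter` EM
#' updates have been spent (defaults 1e-7 and 500, the study's
#' convergence rule). By default the EM sequence is accelerated with
#' monotone SQUAREM-style extrapolation: after two EM updates a step along
#' the squared iteration difference is attempted and kept only when a
#' stabilizing EM update of the extrapolated point does not decrease the
#' log-likelihood, so the reported trace is always non-decreasing and
#' every accepted iterate is an EM update of a feasible point. This
#' matters in weakly separated conditions (few, low-quality indicators),
#' where plain EM's geometric convergence factor approaches 1 and the
#' iteration budget would otherwise misclassify slowly converging
#' solutions as non-converged. A class collapsing to negligible posterior
#' mass is recorded as non-convergence rather than an error.
#'
#' @param d An `lca_dataset`.
#' @param start An `lca_params` of starting values (in simulation runs,
#'   the true population parameters).
#' @param max_iter Maximum EM updates (E+M map evaluations; extrapolation
#'   cycles spend three).
#' @param tol Absolute log-likelihood change declaring convergence.
#' @param boundary_eps Tolerance for [detect_boundary()] on the final
#'   estimate.
#' @param accelerate Use SQUAREM-style extrapolation (plain EM when
#'   `FALSE`).
#' @return An object of class `lca_fit`: `estimate` (`lca_params`),
#'   `posterior`, `loglik` (final value), `loglik_trace`, `converged`,
#'   `n_iterations` (EM updates spent), `failure` (`NA` or
#'   `"degenerate_class"`), `boundary_mask`, `boundary_count`.
#' @export
fit_lca <- function(d, start, max_iter = 500, tol = 1e-7, boundary_eps = 1e-4,
                    accelerate = TRUE) {
  stopifnot(inherits(d, "lca_dataset"), inherits(start, "lca_params"))
  has_cov <- start$has_covariate

  degenerate <- structure(list(), class = "lca_degenerate_marker")
  em_map <- function(params) {
    tryCatch(
      m_step(e_step(params, d), d, has_covariate = has_cov),
      lca_degenerate_class = function(e) degenerate
    )
  }
  is_degenerate <- function(x) inherits(x, "lca_degenerate_marker")

  params <- start
  trace <- numeric(0)
  ll_old <- lca_loglikelihood(start, d)
  converged <- FALSE
  failure <- NA_character_
  n_maps <- 0L

  push <- function(p) {
    # one accepted iterate: append its log-likelihood, test the stopping rule
    ll <- lca_loglikelihood(p, d)
    trace[length(trace) + 1L] <<- ll
    if (is.finite(ll) && is.finite(ll_old) && abs(ll - ll_old) < tol)
      converged <<- TRUE
    ll_old <<- ll
  }

  while (n_maps < max_iter && !converged && is.na(failure)) {
    p0 <- params
    p1 <- em_map(p0); n_maps <- n_maps + 1L
    if (is_degenerate(p1)) { failure <- "degenerate_class"; break }
    push(p1)
    params <- p1
    if (converged || !accelerate || n_maps + 2L > max_iter) next

    p2 <- em_map(p1); n_maps <- n_maps + 1L
    if (is_degenerate(p2)) { failure <- "degenerate_class"; break }
    push(p2)
    params <- p2
    if (converged) break

    # squared-iteration extrapolation through the last three iterates
    t0 <- .pack_params(p0)
    t1 <- .pack_params(p1)
    t2 <- .pack_params(p2)
    r <- t1 - t0
    v <- (t2 - t1) - r
    nv <- sqrt(sum(v^2))
    if (nv < 1e-14) next
    alpha <- min(-sqrt(sum(r^2)) / nv, -1) # step at least as far as plain EM
    cand <- .unpack_params(t0 - 2 * alpha * r + alpha^2 * v, p2)
    p3 <- em_map(cand); n_maps <- n_maps + 1L
    if (is_degenerate(p3)) next # reject the extrapolation, keep p2
    ll3 <- lca_loglikelihood(p3, d)
    if (is.finite(ll3) && ll3 >= ll_old) {
      push(p3)
      params <- p3
    }
  }

  posterior <- tryCatch(e_step(params, d), error = function(e) NULL)
  bd <- detect_boundary(params, eps = boundary_eps)
  structure(
    list(estimate = params,
         posterior = posterior,
         loglik = if (length(trace)) trace[length(trace)] else -Inf,
         loglik_trace = trace,
         converged = converged && is.na(failure),
         n_iterations = n_maps,
         failure = failure,
         boundary_mask = bd$mask,
         boundary_count = bd$count),
    class = "lca_fit"
  )
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("<lca fit: %d classes, loglik %.4f, %s in %d iterations, %d boundary CRP%s>\n",
              x$estimate$n_classes, x$loglik,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$boundary_count,
              if (x$boundary_count == 1) "" else "s"))
  invisible(x)
}

#' Flag boundary CRP estimates
#'
#' A conditional response probability is a boundary estimate when it is
#' estimated at (numerically) exactly 0 or 1, i.e. within `eps` of the
#' edge of the parameter space.
#'
#' @param params An `lca_params` (or an `lca_fit`, whose estimate is used).
#' @param eps Numerical tolerance defining "exactly" 0 or 1.
#' @return A list with `mask` (C x J logical) and `count`.
#' @export
detect_boundary <- function(params, eps = 1e-4) {
  if (inherits(params, "lca_fit")) params <- params$estimate
  mask <- params$crp <= eps | params$crp >= 1 - eps
  list(mask = mask, count = sum(mask))
}
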