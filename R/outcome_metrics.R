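# Dependent variables of the simulation study: absolute relative parameter
# bias (class proportions, CRPs, covariate slope), boundary-estimate
# prevalence, and effect-size summaries (eta squared for continuous
# outcomes, odds ratios for binary outcomes) over the factorial design.

#' Absolute relative bias
#'
#' `|estimate - truth| / |truth|`. Undefined for a true value of zero.
#' Equal raw errors translate into larger relative bias for parameters
#' with smaller population values.
#'
#' @param est Estimate(s).
#' @param truth True value(s), nonzero; recycled against `est`.
#' @return Numeric absolute relative bias.
#' @export
relative_bias <- function(est, truth) {
  if (any(truth == 0))
    stop("relative bias is undefined for a true value of 0")
  abs(est - truth) / abs(truth)
}

# Row/column positions (class-major order: class 1's items, then class
# 2's, ...) of the first `k` CRPs whose population value equals `value`.
.crp_positions <- function(spec, value, k = 2L) {
  pos <- which(abs(t(spec$crp) - value) < 1e-12) # J x C scan => class-major
  if (length(pos) < k)
    stop("population has fewer than ", k, " CRPs at level ", value)
  pos <- pos[seq_len(k)]
  # convert class-major linear index back to (class, item)
  J <- spec$n_indicators
  cbind(class = (pos - 1L) %/% J + 1L, item = (pos - 1L) %% J + 1L)
}

#' CRP bias for high- and low-level items
#'
#' Averages the absolute relative bias over a fixed pair of CRPs whose
#' population value is the quality level's high value, and a fixed pair
#' at the low value — the first two of each in class-major order — so the
#' metric is comparable across models with different numbers of
#' indicators. Boundary estimates are included.
#'
#' @param est An `lca_params` (aligned to the generating labels) or an
#'   `lca_fit`.
#' @param spec The generating `lca_pop_spec`.
#' @return Named numeric vector `c(high = ..., low = ...)`.
#' @export
crp_bias <- function(est, spec) {
  if (inherits(est, "lca_fit")) est <- est$estimate
  lv <- range(spec$crp) # low, high population CRP values
  bias_at <- function(value) {
    idx <- .crp_positions(spec, value)
    mean(relative_bias(est$crp[idx], spec$crp[idx]))
  }
  c(high = bias_at(lv[2]), low = bias_at(lv[1]))
}

#' Structural-parameter bias
#'
#' Without a covariate, the absolute relative bias of each estimated
#' class proportion. With a covariate, the class-proportion role is
#' played by the logit intercepts (conditional class proportions at the
#' covariate mean), so their bias is reported per non-reference class;
#' the slope bias is the relative bias of the single slope in 2-class
#' models and the average over the two (identically generated) slopes in
#' 3-class models.
#'
#' @param est An `lca_params` (aligned to the generating labels) or an
#'   `lca_fit`.
#' @param spec The generating `lca_pop_spec`.
#' @return A list with `class` (named numeric vector of per-class bias)
#'   and `slope` (single numeric, `NA` without a covariate).
#' @export
structural_bias <- function(est, spec) {
  if (inherits(est, "lca_fit")) est <- est$estimate
  C <- spec$n_classes
  if (spec$has_covariate) {
    k <- seq_len(C - 1L)
    cls <- relative_bias(est$beta0[k], spec$beta0[k])
    names(cls) <- paste0("class", k)
    slope <- mean(relative_bias(est$beta1[k], spec$beta1[k]))
  } else {
    cls <- relative_bias(est$gamma, spec$class_proportions)
    names(cls) <- paste0("class", seq_len(C))
    slope <- NA_real_
  }
  list(class = cls, slope = slope)
}

#' Boundary-estimate prevalence over replications
#'
#' Mean over replications of the fraction of the C x J independent CRPs
#' flagged at the 0/1 boundary.
#'
#' @param boundary_counts Integer vector, one boundary count per (usable)
#'   replication.
#' @param n_params Number of CRP parameters per model (C x J).
#' @return Proportion in \[0, 1\].
#' @export
boundary_prevalence <- function(boundary_counts, n_params) {
  if (!length(boundary_counts)) return(NA_real_)
  mean(boundary_counts / n_params)
}

# Normalize an ANOVA term so "quality:covariate" and "covariate:quality"
# match.
.normalize_term <- function(term) {
  paste(sort(trimws(strsplit(term, ":")[[1]])), collapse = ":")
}

.check_balanced <- function(data, factors) {
  counts <- table(data[factors])
  if (length(unique(as.integer(counts))) != 1L)
    stop("design is unbalanced over ", paste(factors, collapse = ", "),
         "; the sums-of-squares decomposition assumes balance")
}

#' Eta-squared effect size from a balanced factorial decomposition
#'
#' Fits the full factorial fixed-effects ANOVA of `outcome` on the given
#' factors and returns `SS_effect / SS_total` for the requested main
#' effect or interaction. Requires a balanced layout (guaranteed for
#' included cells by the harness refill policy), under which the
#' decomposition is orthogonal and order-free. A constant outcome has
#' zero total sum of squares and returns 0 by convention.
#'
#' @param data Data frame of outcomes with factor columns.
#' @param outcome Name of the numeric outcome column.
#' @param term Effect of interest, e.g. `"quality"` or
#'   `"quality:sample_size"`.
#' @param factors Character vector of design-factor columns; defaults to
#'   the standard four when present.
#' @return A single numeric in \[0, 1\].
#' @export
eta_squared <- function(data, outcome, term,
                        factors = intersect(c("sample_size", "n_indicators",
                                              "quality", "covariate"),
                                            names(data))) {
  stopifnot(outcome %in% names(data), length(factors) >= 1)
  df <- data
  for (f in factors) df[[f]] <- factor(df[[f]])
  .check_balanced(df, factors)
  y <- df[[outcome]]
  ss_total <- sum((y - mean(y))^2)
  if (ss_total == 0) return(0)
  form <- stats::as.formula(paste(outcome, "~", paste(factors, collapse = "*")))
  # only the sums of squares are used, so the F-test warning for a
  # saturated (cell-mean) layout is irrelevant
  tab <- suppressWarnings(stats::anova(stats::aov(form, data = df)))
  terms_norm <- vapply(rownames(tab), .normalize_term, character(1))
  want <- .normalize_term(term)
  hit <- which(terms_norm == want)
  if (!length(hit))
    stop("term '", term, "' not in the factorial decomposition")
  tab[hit, "Sum Sq"] / ss_total
}

#' Odds-ratio effect size from a logistic regression
#'
#' Fits a maximum-likelihood logistic regression of a binary outcome on
#' the design factors, each entered as a single ordinal predictor
#' rescaled to \[0, 1\] (so one coefficient per factor), and returns the
#' exponentiated coefficient of the requested term. Interactions are
#' products of the rescaled predictors. Complete separation is reported
#' via the `separated` flag with an infinite odds ratio.
#'
#' @param data Data frame with a 0/1 outcome column and factor columns;
#'   factor columns may be ordered factors or numeric/character with
#'   naturally ordered unique values.
#' @param outcome Name of the binary outcome column.
#' @param term Effect of interest (main effect or `a:b` interaction).
#' @param factors Design-factor columns entered into the model.
#' @return A list with `or` (odds ratio), `coef` (log odds ratio) and
#'   `separated` (logical).
#' @export
or_effect <- function(data, outcome, term,
                      factors = intersect(c("sample_size", "n_indicators",
                                            "quality", "covariate"),
                                          names(data))) {
  stopifnot(outcome %in% names(data))
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1")
  df <- data.frame(.y = y)
  for (f in factors) df[[f]] <- .rescale_ordinal(.canonical_order(data[[f]], f))
  main <- strsplit(term, ":")[[1]]
  if (!all(main %in% factors))
    stop("term '", term, "' uses factors not in the model")
  rhs <- unique(c(factors, if (length(main) > 1) paste(main, collapse = ":")))
  form <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df),
    warning = function(w) invokeRestart("muffleWarning")
  )
  cf <- stats::coef(fit)
  nm <- if (length(main) > 1) paste(main, collapse = ":") else term
  if (!nm %in% names(cf)) {
    alt <- paste(rev(main), collapse = ":")
    if (alt %in% names(cf)) nm <- alt else stop("term '", term, "' not fitted")
  }
  b <- cf[[nm]]
  separated <- !fit$converged || abs(b) > 15
  list(or = if (separated) (if (b > 0) Inf else 0) else exp(b),
       coef = b, separated = separated)
}

# The design's named ordinal factors carry a substantive weak-to-strong
# order that alphabetical sorting would scramble; restore it for plain
# character columns (e.g. after a CSV round trip).
.canonical_order <- function(x, name) {
  canon <- list(quality = .quality_levels, covariate = .covariate_levels)
  if (!is.factor(x) && !is.numeric(x) && name %in% names(canon))
    x <- factor(x, levels = intersect(canon[[name]], unique(x)))
  x
}

# Map an ordinal factor (ordered factor, or numeric/character levels in
# natural order) onto equally spaced scores in [0, 1].
.rescale_ordinal <- function(x) {
  if (is.factor(x)) lev <- levels(x)
  else lev <- sort(unique(x))
  k <- match(as.character(x), as.character(lev))
  if (length(lev) == 1) return(rep(0, length(x)))
  (k - 1) / (length(lev) - 1)
}
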