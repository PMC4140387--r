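# Per-replication diagnostics: did the fitted solution keep the generating
# class labels, switch them by a recoverable permutation, or lose so much
# class-assignment accuracy that no labeling can be trusted (incorrigible)?

# All permutations of 1..n (n <= 3 in this design, but general).
.permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in .permutations(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Class assignment matrix
#'
#' Cross-classifies generating (true) classes against modal posterior
#' classes: entry (t, e) is the proportion of observations generated in
#' class t whose highest-posterior class is e. Rows sum to 1. Posterior
#' ties are broken toward the lower class index.
#'
#' @param fit An `lca_fit` (or an N x C posterior matrix).
#' @param d An `lca_dataset` carrying `true_class`.
#' @return A C x C row-stochastic matrix.
#' @export
assignment_matrix <- function(fit, d) {
  posterior <- if (inherits(fit, "lca_fit")) fit$posterior else as.matrix(fit)
  stopifnot(!is.null(d$true_class))
  C <- ncol(posterior)
  modal <- max.col(posterior, ties.method = "first")
  A <- matrix(0, C, C)
  for (t in seq_len(C)) {
    idx <- d$true_class == t
    if (!any(idx)) next
    tab <- tabulate(modal[idx], nbins = C)
    A[t, ] <- tab / sum(tab)
  }
  A
}

#' Classify a solution's labeling from its assignment matrix
#'
#' Searches all permutations of the estimated classes for the one
#' maximizing the sum of matched-class assignment proportions (the trace
#' of the column-permuted matrix). If the best permutation's per-class
#' accuracy falls below `accuracy_floor` for any class, or the maximizing
#' permutation is not unique, the labeling cannot be trusted and the
#' solution is incorrigible. Otherwise the solution is correctly labeled
#' (identity permutation) or label-switched (any other permutation).
#'
#' @param A C x C row-stochastic assignment matrix from
#'   [assignment_matrix()].
#' @param accuracy_floor Minimum matched-class assignment accuracy
#'   required of every class.
#' @return A list with `status` (`"correct"`, `"switched"` or
#'   `"incorrigible"`) and `permutation` (the map from true class to
#'   estimated class; `NULL` when incorrigible).
#' @export
classify_labels <- function(A, accuracy_floor = 0.7) {
  C <- nrow(A)
  perms <- .permutations(C)
  scores <- vapply(perms, function(p) sum(A[cbind(seq_len(C), p)]), numeric(1))
  best <- max(scores)
  winners <- which(scores >= best - 1e-12)
  if (length(winners) > 1L)
    return(list(status = "incorrigible", permutation = NULL))
  p <- perms[[winners]]
  diag_acc <- A[cbind(seq_len(C), p)]
  if (min(diag_acc) < accuracy_floor)
    return(list(status = "incorrigible", permutation = NULL))
  if (all(p == seq_len(C)))
    list(status = "correct", permutation = p)
  else
    list(status = "switched", permutation = p)
}

#' Apply a class permutation to a parameter set
#'
#' Reorders classes so that estimated class `perm[t]` becomes class t.
#' Logit coefficients are re-expressed against the new reference (last)
#' class.
#'
#' @param params An `lca_params`.
#' @param perm Permutation of 1..C mapping true class to estimated class.
#' @return An `lca_params` with classes reordered.
#' @export
permute_params <- function(params, perm) {
  stopifnot(inherits(params, "lca_params"), length(perm) == params$n_classes)
  crp <- params$crp[perm, , drop = FALSE]
  if (params$has_covariate) {
    b0 <- params$beta0[perm]; b1 <- params$beta1[perm]
    C <- length(b0)
    parameter_set(crp, beta0 = b0 - b0[C], beta1 = b1 - b1[C])
  } else {
    parameter_set(crp, gamma = params$gamma[perm])
  }
}

#' Classify one replication through the exclusion cascade
#'
#' Applies the study's four-rule cascade in order of precedence:
#' zero-variance items, non-convergence, then labeling (incorrigible /
#' switched / ok). Statuses are mutually exclusive. Label-switched
#' solutions are flagged for exclusion, not relabeled.
#'
#' @param fit An `lca_fit`, or `NULL` when estimation failed outright.
#' @param d The `lca_dataset` the model was fitted to (with `true_class`).
#' @param accuracy_floor Per-class accuracy floor for [classify_labels()].
#' @return A list with `status` (one of `"zero_variance"`,
#'   `"nonconverged"`, `"incorrigible"`, `"label_switched"`, `"ok"`) and
#'   `permutation` (identity for ok, the detected permutation for
#'   switched, `NULL` otherwise).
#' @export
classify_replication <- function(fit, d, accuracy_floor = 0.7) {
  if (zero_variance_check(d)$any)
    return(list(status = "zero_variance", permutation = NULL))
  if (is.null(fit) || !isTRUE(fit$converged))
    return(list(status = "nonconverged", permutation = NULL))
  lab <- classify_labels(assignment_matrix(fit, d), accuracy_floor)
  switch(lab$status,
    incorrigible = list(status = "incorrigible", permutation = NULL),
    switched = list(status = "label_switched", permutation = lab$permutation),
    correct = list(status = "ok", permutation = lab$permutation)
  )
}
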