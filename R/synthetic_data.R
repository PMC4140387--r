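#' Derive a replication seed
#'
#' Deterministic seed derivation from a root seed, a cell index and a
#' replication index, so that refilled replications and reordered or
#' parallel cell execution never share streams. The result is a positive
#' integer below 2^31 - 1.
#'
#' @param root_seed Integer root seed for the whole run.
#' @param cell_index Integer index of the design cell.
#' @param rep_index Integer replication counter within the cell (refill
#'   batches keep counting upwards, so new batches get fresh seeds).
#' @return A single integer seed.
#' @export
derive_seed <- function(root_seed, cell_index, rep_index) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(root_seed) %% m) * 48271 %% m
  s <- (s + as.double(cell_index) * 69621) %% m
  s <- (s * 48271 + as.double(rep_index) * 16807) %% m
  as.integer(s %% (m - 1L) + 1L)
}

#' Generate one replication dataset from a population specification
#'
#' Draws `n` observations: an optional standard-normal covariate, a latent
#' class from the multinomial-logit model `softmax(beta0 + beta1 * x)`
#' (which reduces to the unconditional proportions when all slopes are
#' zero), and binary item responses that are independent Bernoulli draws
#' given the class, with success probability the class's CRP.
#'
#' @param spec An `lca_pop_spec`.
#' @param n Number of observations.
#' @param seed Integer seed; the draw is fully reproducible given the seed.
#' @return An object of class `lca_dataset`: a list with `responses`
#'   (n x J 0/1 matrix), `x` (numeric covariate or `NULL`), `true_class`
#'   (integer vector, kept for diagnostics only, never used in
#'   estimation) and `seed`.
#' @export
generate_dataset <- function(spec, n, seed) {
  stopifnot(inherits(spec, "lca_pop_spec"), n >= 1)
  set.seed(as.integer(seed))
  C <- spec$n_classes
  J <- spec$n_indicators
  if (spec$has_covariate) {
    x <- stats::rnorm(n)
    eta <- outer(x, spec$beta1) + rep(spec$beta0, each = n) # n x C
    mx <- eta[, 1]
    for (j in seq_len(C)[-1]) mx <- pmax(mx, eta[, j])
    p <- exp(eta - mx)
    p <- p / rowSums(p)
    u <- stats::runif(n)
    cum <- p
    for (j in seq_len(C)[-1]) cum[, j] <- cum[, j - 1] + p[, j]
    true_class <- as.integer(1L + rowSums(u > cum))
    true_class[true_class > C] <- C # guard against rounding at the top end
  } else {
    x <- NULL
    true_class <- sample.int(C, n, replace = TRUE, prob = spec$class_proportions)
  }
  prob <- spec$crp[true_class, , drop = FALSE]
  responses <- matrix(as.integer(stats::runif(n * J) < prob), nrow = n, ncol = J)
  colnames(responses) <- paste0("y", seq_len(J))
  structure(
    list(responses = responses, x = x, true_class = true_class, seed = as.integer(seed)),
    class = "lca_dataset"
  )
}

#' @export
print.lca_dataset <- function(x, ...) {
  cat(sprintf("<dataset: n = %d, J = %d%s, seed = %d>\n",
              nrow(x$responses), ncol(x$responses),
              if (!is.null(x$x)) ", covariate" else "", x$seed))
  invisible(x)
}

#' Exact response-pattern probabilities (brute-force oracle)
#'
#' Enumerates all 2^J binary response patterns and computes each pattern's
#' probability under the mixture, `sum_c gamma_c prod_j crp^y (1-crp)^(1-y)`.
#' With a covariate population a covariate value must be supplied and the
#' class prior is evaluated conditionally at that value. Intended as an
#' independent check of the likelihood machinery for small J.
#'
#' @param spec An `lca_pop_spec`.
#' @param x Optional single covariate value at which to condition the
#'   class prior; required when the spec has a covariate.
#' @return A data frame with one row per pattern: columns `y1..yJ` and
#'   `prob`. Probabilities sum to 1.
#' @export
pattern_probabilities <- function(spec, x = NULL) {
  stopifnot(inherits(spec, "lca_pop_spec"))
  J <- spec$n_indicators
  if (J > 20)
    stop("pattern enumeration limited to J <= 20 (got ", J, ")")
  if (spec$has_covariate && is.null(x))
    stop("spec has a covariate: supply the covariate value x at which to condition")
  if (!is.null(x)) {
    prior <- softmax(spec$beta0 + spec$beta1 * x)
  } else {
    prior <- spec$class_proportions
  }
  patterns <- as.matrix(expand.grid(rep(list(0:1), J), KEEP.OUT.ATTRS = FALSE))
  colnames(patterns) <- paste0("y", seq_len(J))
  # per-class pattern probabilities: 2^J x C
  percls <- sapply(seq_len(spec$n_classes), function(c) {
    p <- spec$crp[c, ]
    exp(patterns %*% log(p) + (1 - patterns) %*% log(1 - p))
  })
  prob <- as.numeric(percls %*% prior)
  out <- as.data.frame(patterns)
  out$prob <- prob
  out
}

#' Flag observed items with zero variance
#'
#' An item has zero variance when all sampled responses are identical,
#' which makes the replication unusable; this occurs by sampling error in
#' small, high-quality samples.
#'
#' @param d An `lca_dataset` or a 0/1 response matrix.
#' @return A list with `item` (logical flag per item) and `any` (overall
#'   flag).
#' @export
zero_variance_check <- function(d) {
  y <- if (inherits(d, "lca_dataset")) d$responses else as.matrix(d)
  item <- apply(y, 2, function(col) all(col == col[1]))
  list(item = item, any = any(item))
}

#' Write a dataset to CSV
#'
#' Columns `y1..yJ`, then `x` when a covariate is present, then
#' `true_class` unless dropped.
#'
#' @param d An `lca_dataset`.
#' @param path Output file path.
#' @param keep_true_class Include the generating class labels (diagnostics
#'   only).
#' @export
write_dataset_csv <- function(d, path, keep_true_class = TRUE) {
  stopifnot(inherits(d, "lca_dataset"))
  df <- as.data.frame(d$responses)
  if (!is.null(d$x)) df$x <- d$x
  if (keep_true_class) df$true_class <- d$true_class
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset from CSV
#'
#' Expects the layout written by [write_dataset_csv()]: item columns
#' `y1..yJ`, optional `x`, optional `true_class`.
#'
#' @param path CSV file path.
#' @return An `lca_dataset` (with `seed = NA`).
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path)
  ycols <- grep("^y[0-9]+$", names(df), value = TRUE)
  responses <- as.matrix(df[, ycols, drop = FALSE])
  if (!all(responses %in% c(0L, 1L)))
    stop("item responses must be binary 0/1")
  structure(
    list(responses = responses,
         x = if ("x" %in% names(df)) df$x else NULL,
         true_class = if ("true_class" %in% names(df)) as.integer(df$true_class) else NULL,
         seed = NA_integer_),
    class = "lca_dataset"
  )
}
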