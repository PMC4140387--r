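# Factor levels of the simulation design. Quality and covariate levels are
# ordered from weakest to strongest so that ordinal effect-size coding is
# well defined downstream.
.sample_sizes <- c(70L, 100L, 200L, 300L, 500L, 1000L, 2000L)
.indicator_counts <- 4:12
.quality_levels <- c("low", "moderate", "high")
.covariate_levels <- c("none", "small", "moderate", "large")

# High/low conditional response probability (CRP) pair per quality level.
.quality_crp <- list(
  low      = c(high = 0.7, low = 0.3),
  moderate = c(high = 0.8, low = 0.2),
  high     = c(high = 0.9, low = 0.1)
)

# Items for which Class 2 has a HIGH response probability; the remaining
# items are low. The assignment alternates in pairs up to 12 indicators and
# is truncated to the first J items for smaller models.
.class2_high_items <- c(1L, 2L, 5L, 7L, 9L, 11L)

# Odds ratio of the covariate effect on class membership, by named level.
.covariate_or <- c(none = 1, small = 1.5, moderate = 2.5, large = 4)

#' Construct a design cell
#'
#' A design cell is one condition of the factorial simulation design:
#' number of latent classes, sample size, number of binary indicators,
#' indicator quality, and covariate effect-size level.
#'
#' @param n_classes Number of latent classes, 2 or 3.
#' @param sample_size One of 70, 100, 200, 300, 500, 1000, 2000.
#' @param n_indicators Number of binary indicators, between 4 and 12.
#'   Three-class models with 4 indicators are rejected as underidentified.
#' @param quality Indicator quality: `"low"`, `"moderate"` or `"high"`,
#'   mapping to CRP pairs (0.7, 0.3), (0.8, 0.2) and (0.9, 0.1).
#' @param covariate Covariate effect size: `"none"`, `"small"`,
#'   `"moderate"` or `"large"` (odds ratios 1, 1.5, 2.5, 4).
#' @return An object of class `lca_design_cell` (a named list).
#' @export
#' @examples
#' design_cell(2, 500, 8, "high", "none")
design_cell <- function(n_classes, sample_size, n_indicators, quality, covariate) {
  n_classes <- as.integer(n_classes)
  sample_size <- as.integer(sample_size)
  n_indicators <- as.integer(n_indicators)
  if (!n_classes %in% c(2L, 3L))
    stop("n_classes must be 2 or 3, got ", n_classes)
  if (!sample_size %in% .sample_sizes)
    stop("sample_size must be one of ", paste(.sample_sizes, collapse = ", "),
         ", got ", sample_size)
  if (!n_indicators %in% .indicator_counts)
    stop("n_indicators must be between 4 and 12, got ", n_indicators)
  if (n_classes == 3L && n_indicators == 4L)
    stop("3-class models with 4 indicators are underidentified and not part of the design")
  quality <- match.arg(quality, .quality_levels)
  covariate <- match.arg(covariate, .covariate_levels)
  structure(
    list(n_classes = n_classes, sample_size = sample_size,
         n_indicators = n_indicators, quality = quality, covariate = covariate),
    class = "lca_design_cell"
  )
}

#' @export
print.lca_design_cell <- function(x, ...) {
  cat(sprintf("<design cell: %d classes, N = %d, J = %d, %s quality, %s covariate>\n",
              x$n_classes, x$sample_size, x$n_indicators, x$quality, x$covariate))
  invisible(x)
}

#' Convert a covariate effect-size level to a logistic slope
#'
#' Effect sizes follow odds-ratio conventions: OR = 1.5, 2.5 and 4 for
#' small, moderate and large effects. The slope is `log(OR)`; the `"none"`
#' level yields slope 0.
#'
#' @param level One of `"none"`, `"small"`, `"moderate"`, `"large"`.
#' @return The logistic regression slope, a single numeric.
#' @export
or_to_slope <- function(level) {
  level <- match.arg(level, .covariate_levels)
  log(.covariate_or[[level]])
}

#' Convert class proportions to multinomial-logit intercepts
#'
#' Returns intercepts `beta0_c = log(gamma_c / gamma_C)` with the last class
#' as reference (its intercept is exactly 0), so that the softmax of the
#' intercepts reproduces the proportions. With a standard-normal covariate
#' these intercepts make the conditional class proportions at the covariate
#' mean equal the unconditional proportions.
#'
#' @param gamma Probability vector summing to 1, all entries strictly positive.
#' @return Numeric vector of intercepts, the last entry 0.
#' @export
proportions_to_intercepts <- function(gamma) {
  if (any(gamma <= 0))
    stop("class proportions must be strictly positive to define intercepts")
  if (abs(sum(gamma) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  b <- log(gamma / gamma[length(gamma)])
  b[length(b)] <- 0
  b
}

#' Softmax transform
#'
#' @param eta Numeric vector of linear predictors.
#' @return Probability vector summing to 1.
#' @export
softmax <- function(eta) {
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Generic population-specification constructor
#'
#' Builds an `lca_pop_spec` from arbitrary class proportions and a CRP
#' matrix; [build_population_spec()] is the constructor for the study's own
#' populations. Validation enforces the model constraints but not the
#' study's profile scheme.
#'
#' @param class_proportions Probability vector of length C.
#' @param crp C x J matrix of conditional response probabilities
#'   (probability of endorsing category 1), all entries in (0, 1).
#' @param slope Covariate slopes of length C with the last entry 0, or
#'   `NULL` for an unconditional population.
#' @param quality,covariate Optional level labels carried along for
#'   bookkeeping.
#' @return An object of class `lca_pop_spec`.
#' @export
population_spec <- function(class_proportions, crp, slope = NULL,
                            quality = NA_character_, covariate = NA_character_) {
  crp <- as.matrix(crp)
  C <- length(class_proportions)
  if (nrow(crp) != C)
    stop("crp must have one row per class")
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  if (any(class_proportions <= 0))
    stop("class proportions must be strictly positive")
  if (any(crp <= 0 | crp >= 1))
    stop("all conditional response probabilities must lie strictly in (0, 1)")
  has_covariate <- !is.null(slope) && any(slope != 0)
  if (is.null(slope)) slope <- rep(0, C)
  if (length(slope) != C || slope[C] != 0)
    stop("slope must have length C with the reference (last) class fixed at 0")
  structure(
    list(
      n_classes = C,
      n_indicators = ncol(crp),
      class_proportions = as.numeric(class_proportions),
      crp = crp,
      beta0 = proportions_to_intercepts(class_proportions),
      beta1 = as.numeric(slope),
      has_covariate = has_covariate,
      quality = quality,
      covariate = covariate
    ),
    class = "lca_pop_spec"
  )
}

#' @export
print.lca_pop_spec <- function(x, ...) {
  cat(sprintf("<population spec: %d classes, %d indicators%s>\n",
              x$n_classes, x$n_indicators,
              if (x$has_covariate) ", covariate" else ""))
  cat("  class proportions:", paste(format(x$class_proportions), collapse = " "), "\n")
  invisible(x)
}

#' Build the generating population for a design cell
#'
#' Class profiles follow the study scheme: Class 1 has high CRPs for all
#' items; Class 2 has high CRPs for items 1, 2, 5, 7, 9 and 11 (truncated
#' to the first J items) and low CRPs otherwise; in 3-class populations
#' Class 3 has low CRPs for all items. Class proportions are (0.67, 0.33)
#' for two classes and (0.4, 0.4, 0.2) for three. The covariate slope is
#' `log(OR)` of the cell's covariate level, equal for all non-reference
#' classes, and the intercepts reproduce the unconditional proportions at
#' the covariate mean.
#'
#' @param cell An [design_cell()] object.
#' @return An object of class `lca_pop_spec`.
#' @export
#' @examples
#' build_population_spec(design_cell(2, 500, 8, "high", "none"))
build_population_spec <- function(cell) {
  stopifnot(inherits(cell, "lca_design_cell"))
  J <- cell$n_indicators
  pair <- .quality_crp[[cell$quality]]
  hi <- pair[["high"]]; lo <- pair[["low"]]
  class2 <- ifelse(seq_len(J) %in% .class2_high_items, hi, lo)
  if (cell$n_classes == 2L) {
    gamma <- c(0.67, 0.33)
    crp <- rbind(rep(hi, J), class2)
  } else {
    gamma <- c(0.4, 0.4, 0.2)
    crp <- rbind(rep(hi, J), class2, rep(lo, J))
  }
  dimnames(crp) <- list(paste0("class", seq_len(cell$n_classes)),
                        paste0("y", seq_len(J)))
  slope <- c(rep(or_to_slope(cell$covariate), cell$n_classes - 1L), 0)
  population_spec(gamma, crp, slope,
                  quality = cell$quality, covariate = cell$covariate)
}

#' Enumerate the full factorial design
#'
#' Crosses sample size (7 levels), number of indicators (4-12), indicator
#' quality (3 levels) and covariate effect (4 levels) for 2- and 3-class
#' models, omitting the underidentified 3-class/4-indicator cells: 756
#' two-class plus 672 three-class conditions, 1428 in total. Rows are
#' sorted by n_classes, sample_size, n_indicators, quality, covariate
#' (levels in increasing strength), giving a stable, duplicate-free order.
#'
#' @return A data frame with one row per design cell and columns
#'   `n_classes`, `sample_size`, `n_indicators`, `quality`, `covariate`.
#' @export
enumerate_design <- function() {
  grid <- expand.grid(
    covariate = .covariate_levels,
    quality = .quality_levels,
    n_indicators = .indicator_counts,
    sample_size = .sample_sizes,
    n_classes = c(2L, 3L),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[!(grid$n_classes == 3L & grid$n_indicators == 4L), ]
  grid <- grid[, c("n_classes", "sample_size", "n_indicators", "quality", "covariate")]
  grid$quality <- factor(grid$quality, levels = .quality_levels)
  grid$covariate <- factor(grid$covariate, levels = .covariate_levels)
  grid <- grid[order(grid$n_classes, grid$sample_size, grid$n_indicators,
                     grid$quality, grid$covariate), ]
  rownames(grid) <- NULL
  grid
}

#' Turn one row of the design grid into a design cell
#'
#' @param row A one-row data frame as returned by [enumerate_design()].
#' @return An `lca_design_cell`.
#' @export
cell_from_row <- function(row) {
  design_cell(row$n_classes, row$sample_size, row$n_indicators,
              as.character(row$quality), as.character(row$covariate))
}

#' Serialize a population specification to JSON
#'
#' @param spec An `lca_pop_spec`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "lca_pop_spec"))
  x <- list(
    n_classes = spec$n_classes,
    n_indicators = spec$n_indicators,
    class_proportions = spec$class_proportions,
    crp = unname(spec$crp),
    beta1 = spec$beta1,
    quality = spec$quality,
    covariate = spec$covariate
  )
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Deserialize a population specification from JSON
#'
#' @param json A JSON string or path to a JSON file written by
#'   [spec_to_json()].
#' @return An `lca_pop_spec`.
#' @export
spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  population_spec(x$class_proportions, x$crp, x$beta1,
                  quality = x$quality %||% NA_character_,
                  covariate = x$covariate %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export the design grid to CSV
#'
#' @param path File path for the CSV (one row per design cell).
#' @return The grid data frame, invisibly.
#' @export
write_design_grid <- function(path) {
  grid <- enumerate_design()
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(grid)
}
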