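# Executes design cells under the study's replication policy: a fixed
# initial batch per cell, classification of every replication through the
# exclusion cascade, refill batches sized three times the current shortfall
# until the target number of usable replications is reached, and whole-cell
# exclusion when fewer than half of the initial replications are usable.

.status_levels <- c("ok", "nonconverged", "label_switched", "incorrigible",
                    "zero_variance")

# Run and classify a single replication; returns a one-row data frame.
.one_replication <- function(cell, spec, start, rep_index, seed,
                             accuracy_floor, max_iter, tol, boundary_eps) {
  d <- generate_dataset(spec, cell$sample_size, seed)
  fit <- NULL
  if (!zero_variance_check(d)$any) {
    fit <- tryCatch(
      fit_lca(d, start, max_iter = max_iter, tol = tol,
              boundary_eps = boundary_eps),
      error = function(e) NULL
    )
  }
  cls <- classify_replication(fit, d, accuracy_floor)
  row <- data.frame(
    n_classes = cell$n_classes, sample_size = cell$sample_size,
    n_indicators = cell$n_indicators, quality = cell$quality,
    covariate = cell$covariate,
    rep_index = rep_index, seed = seed, status = cls$status,
    permutation = if (is.null(cls$permutation)) NA_character_
                  else paste(cls$permutation, collapse = ""),
    loglik = if (is.null(fit)) NA_real_ else fit$loglik,
    n_iterations = if (is.null(fit)) NA_integer_ else fit$n_iterations,
    boundary_count = if (is.null(fit)) NA_integer_ else fit$boundary_count,
    class1_bias = NA_real_, class2_bias = NA_real_, class3_bias = NA_real_,
    high_crp_bias = NA_real_, low_crp_bias = NA_real_, slope_bias = NA_real_,
    stringsAsFactors = FALSE
  )
  if (cls$status == "ok") {
    est <- fit$estimate
    cb <- crp_bias(est, spec)
    sb <- structural_bias(est, spec)
    row$high_crp_bias <- cb[["high"]]
    row$low_crp_bias <- cb[["low"]]
    for (k in seq_along(sb$class))
      row[[paste0("class", k, "_bias")]] <- sb$class[[k]]
    row$slope_bias <- sb$slope
  }
  row
}

#' Run all replications for one design cell
#'
#' Generates and fits `target_reps` initial replications (seeds derived
#' from `root_seed` and `cell_index`), classifies each through the
#' exclusion cascade, then applies the cell policy: if fewer than half of
#' the initial replications are usable the cell is excluded outright and
#' never refilled; otherwise refill batches sized three times the current
#' shortfall (with fresh seeds) are generated until `target_reps` usable
#' replications exist or `max_refills` rounds are exhausted.
#'
#' @param cell An `lca_design_cell`.
#' @param target_reps Usable replications required per cell (the study
#'   default is 1000; reduced-scale runs use the same code path).
#' @param root_seed Integer root seed for the run.
#' @param cell_index Integer index of this cell in its grid (seed
#'   derivation input).
#' @param accuracy_floor Per-class assignment accuracy below which a
#'   solution is incorrigible.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param boundary_eps Boundary-detection tolerance.
#' @param max_refills Cap on refill rounds (termination guarantee; hitting
#'   it marks the cell excluded with reason `"refill_exhausted"`).
#' @return A list with `summary` (one-row data frame, see
#'   [summarize_cell()]) and `records` (data frame, one row per
#'   replication run).
#' @export
run_cell <- function(cell, target_reps = 1000, root_seed = 1, cell_index = 1,
                     accuracy_floor = 0.7, max_iter = 500, tol = 1e-7,
                     boundary_eps = 1e-4, max_refills = 10) {
  stopifnot(inherits(cell, "lca_design_cell"), target_reps >= 1)
  spec <- build_population_spec(cell)
  start <- spec_to_params(spec)

  run_batch <- function(rep_indices) {
    do.call(rbind, lapply(rep_indices, function(r) {
      .one_replication(cell, spec, start, r,
                       derive_seed(root_seed, cell_index, r),
                       accuracy_floor, max_iter, tol, boundary_eps)
    }))
  }

  records <- run_batch(seq_len(target_reps))
  records$batch <- 0L
  initial_ok <- sum(records$status == "ok")
  usable_fraction <- initial_ok / target_reps

  refills_used <- 0L
  exclusion_reason <- NA_character_
  if (usable_fraction < 0.5) {
    included <- FALSE
    exclusion_reason <- "under_50pct_usable"
  } else {
    included <- TRUE
    next_rep <- target_reps + 1L
    while (sum(records$status == "ok") < target_reps) {
      if (refills_used >= max_refills) {
        included <- FALSE
        exclusion_reason <- "refill_exhausted"
        break
      }
      shortfall <- target_reps - sum(records$status == "ok")
      batch_reps <- next_rep:(next_rep + 3L * shortfall - 1L)
      next_rep <- next_rep + 3L * shortfall
      refills_used <- refills_used + 1L
      batch <- run_batch(batch_reps)
      batch$batch <- refills_used
      records <- rbind(records, batch)
    }
  }

  summary <- summarize_cell(cell, records, spec, target_reps,
                            included, refills_used, exclusion_reason)
  list(summary = summary, records = records)
}

#' Summarize a cell's replication records
#'
#' Status counts are taken over the initial batch (the basis of the 50%
#' rule and of the non-convergence/incorrigibility outcomes, which the
#' study examines before refilling). Bias and boundary outcomes are
#' averaged over the first `target_reps` usable replications in run
#' order, so every included cell contributes a balanced number.
#'
#' @param cell The `lca_design_cell`.
#' @param records Replication records from [run_cell()].
#' @param spec The generating `lca_pop_spec`.
#' @param target_reps Usable replications the cell should contribute.
#' @param included,refills_used,exclusion_reason Cell policy outcomes.
#' @return A one-row data frame.
#' @export
summarize_cell <- function(cell, records, spec, target_reps,
                           included, refills_used, exclusion_reason) {
  initial <- records[records$batch == 0L, ]
  counts <- table(factor(initial$status, levels = .status_levels))
  ok_all <- records[records$status == "ok", ]
  ok_used <- utils::head(ok_all, target_reps)
  n_params <- spec$n_classes * spec$n_indicators
  mean_or_na <- function(x) if (nrow(ok_used)) mean(x, na.rm = TRUE) else NA_real_
  out <- data.frame(
    n_classes = cell$n_classes, sample_size = cell$sample_size,
    n_indicators = cell$n_indicators, quality = cell$quality,
    covariate = cell$covariate,
    n_initial = nrow(initial),
    n_ok = as.integer(counts[["ok"]]),
    n_nonconverged = as.integer(counts[["nonconverged"]]),
    n_label_switched = as.integer(counts[["label_switched"]]),
    n_incorrigible = as.integer(counts[["incorrigible"]]),
    n_zero_variance = as.integer(counts[["zero_variance"]]),
    prop_nonconverged = counts[["nonconverged"]] / nrow(initial),
    prop_incorrigible = counts[["incorrigible"]] / nrow(initial),
    n_usable = nrow(ok_all),
    included = included,
    refills_used = refills_used,
    exclusion_reason = exclusion_reason,
    boundary_prevalence = if (nrow(ok_used))
      boundary_prevalence(ok_used$boundary_count, n_params) else NA_real_,
    class1_bias = mean_or_na(ok_used$class1_bias),
    class2_bias = mean_or_na(ok_used$class2_bias),
    class3_bias = if (cell$n_classes == 3L) mean_or_na(ok_used$class3_bias)
                  else NA_real_,
    high_crp_bias = mean_or_na(ok_used$high_crp_bias),
    low_crp_bias = mean_or_na(ok_used$low_crp_bias),
    slope_bias = if (cell$covariate != "none") mean_or_na(ok_used$slope_bias)
                 else NA_real_,
    stringsAsFactors = FALSE
  )
  out
}

#' Run a list of design cells
#'
#' Cells execute independently with seeds derived from `(root_seed,
#' cell_index, rep_index)`, so results are identical for any execution
#' order or degree of parallelism. A failure inside one cell is recorded
#' in its summary row and never aborts the grid.
#'
#' @param cells A data frame of cells (rows as from [enumerate_design()])
#'   or a list of `lca_design_cell` objects.
#' @param target_reps,root_seed,... Passed to [run_cell()].
#' @param cell_indices Seed-derivation indices, defaulting to each cell's
#'   row position in `cells`; pass stable indices when running a filtered
#'   subset of a larger grid.
#' @return A list with `summaries` (one row per cell) and `records` (all
#'   replication records).
#' @export
run_grid <- function(cells, target_reps = 1000, root_seed = 1,
                     cell_indices = NULL, ...) {
  if (is.data.frame(cells))
    cells <- lapply(seq_len(nrow(cells)), function(i) cell_from_row(cells[i, ]))
  if (!length(cells))
    return(list(summaries = data.frame(), records = data.frame()))
  if (is.null(cell_indices)) cell_indices <- seq_along(cells)
  stopifnot(length(cell_indices) == length(cells))
  runs <- lapply(seq_along(cells), function(i) {
    tryCatch(
      run_cell(cells[[i]], target_reps = target_reps, root_seed = root_seed,
               cell_index = cell_indices[i], ...),
      error = function(e) {
        cl <- cells[[i]]
        list(summary = data.frame(
          n_classes = cl$n_classes, sample_size = cl$sample_size,
          n_indicators = cl$n_indicators, quality = cl$quality,
          covariate = cl$covariate, n_initial = 0L, n_ok = 0L,
          n_nonconverged = 0L, n_label_switched = 0L, n_incorrigible = 0L,
          n_zero_variance = 0L, prop_nonconverged = NA_real_,
          prop_incorrigible = NA_real_, n_usable = 0L, included = FALSE,
          refills_used = 0L, exclusion_reason = paste("error:", conditionMessage(e)),
          boundary_prevalence = NA_real_, class1_bias = NA_real_,
          class2_bias = NA_real_, class3_bias = NA_real_,
          high_crp_bias = NA_real_, low_crp_bias = NA_real_,
          slope_bias = NA_real_, stringsAsFactors = FALSE),
          records = NULL)
      }
    )
  })
  summaries <- do.call(rbind, lapply(runs, `[[`, "summary"))
  rownames(summaries) <- NULL
  records <- do.call(rbind, Filter(Negate(is.null), lapply(runs, `[[`, "records")))
  list(summaries = summaries, records = records)
}

#' Write harness output to CSV files plus a JSON manifest
#'
#' @param result The list returned by [run_grid()] (or a single
#'   [run_cell()] result).
#' @param dir Output directory, created if needed.
#' @param settings Named list of run settings stored in `manifest.json`.
#' @return The directory path, invisibly.
#' @export
write_run <- function(result, dir, settings = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summaries <- if (is.data.frame(result$summary)) result$summary else result$summaries
  utils::write.csv(summaries, file.path(dir, "cell_summaries.csv"),
                   row.names = FALSE)
  if (!is.null(result$records))
    utils::write.csv(result$records, file.path(dir, "replications.csv"),
                     row.names = FALSE)
  manifest <- c(list(package_version = as.character(utils::packageVersion("lcasim")),
                     written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                settings)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
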