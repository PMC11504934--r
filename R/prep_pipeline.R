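#' Full exposure-curation pipeline
#'
#' Applies, in order: hour/minute combining, low-endorsement filtering of
#' binary exposures, upper-tail outlier removal on flagged continuous
#' exposures, iterative random-forest imputation run separately within the
#' training and testing subsamples, and greedy collinearity pruning decided
#' on the training subsample and applied to both. With `listwise = TRUE`
#' the imputation step is skipped (missing cells stay missing and are
#' handled by list-wise deletion at model time), reproducing the
#' list-wise-deletion sensitivity variant; `outlier_k = Inf` reproduces the
#' no-outlier-removal variant.
#'
#' @param cohort Cohort `data.frame` with a `subsample` column.
#' @param specs `exposure_spec` table.
#' @param endorsement_threshold Binary endorsement cutoff (default 0.01).
#' @param outlier_k Outlier fence multiplier (default 3; `Inf` disables).
#' @param r_threshold Collinearity cutoff (default 0.9).
#' @param listwise Skip imputation when `TRUE`.
#' @param max_iter,n_trees,seed Passed to [impute_missforest()].
#' @return List with `cohort`, `specs` (surviving exposures) and `report`,
#'   a `prep_report` containing `n_input`, `dropped_low_endorsement`,
#'   `dropped_collinear`, `n_retained`, `outliers_removed`,
#'   `imputation_iterations`, `imputation_converged`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_families = 120, n_exposures = 8,
#'                                   n_true_risk = 2, n_true_protective = 0,
#'                                   n_rare = 1, n_collinear_pairs = 1,
#'                                   missing_rate = 0.05, seed = 3))
#' prep <- run_prep(sim$cohort, exposure_specs(sim$truth), n_trees = 10)
#' prep$report
run_prep <- function(cohort, specs,
                     endorsement_threshold = 0.01,
                     outlier_k = 3,
                     r_threshold = 0.9,
                     listwise = FALSE,
                     max_iter = 10L, n_trees = 100L, seed = 1L) {
  stopifnot(inherits(specs, "data.frame"))
  comb <- combine_hour_minute(cohort, specs)
  cohort <- comb$cohort; specs <- comb$specs
  n_input <- nrow(specs)

  filt <- filter_low_endorsement(cohort, specs, endorsement_threshold)
  cohort <- filt$cohort; specs <- filt$specs

  outl <- remove_outliers(cohort, specs, k = outlier_k)
  cohort <- outl$cohort

  iterations <- list(); converged <- list()
  if (!listwise) {
    parts <- lapply(c(train = "train", test = "test"), function(s) {
      sub <- cohort[cohort$subsample == s, , drop = FALSE]
      if (!nrow(sub)) return(list(cohort = sub, iterations = 0L,
                                  converged = TRUE))
      impute_missforest(sub, specs, max_iter = max_iter, n_trees = n_trees,
                        seed = seed + (s == "test"))
    })
    ids <- cohort$participant_id
    cohort <- rbind(parts$train$cohort, parts$test$cohort)
    cohort <- cohort[match(ids, cohort$participant_id), , drop = FALSE]
    rownames(cohort) <- NULL
    iterations <- lapply(parts, `[[`, "iterations")
    converged <- lapply(parts, `[[`, "converged")
  }

  pruned <- prune_collinear(cohort, specs$name, r_threshold = r_threshold)
  cohort <- pruned$cohort
  specs <- specs[!(specs$name %in% pruned$dropped), , drop = FALSE]

  report <- structure(list(
    n_input = n_input,
    dropped_low_endorsement = filt$dropped,
    dropped_collinear = pruned$dropped,
    n_retained = n_input - length(filt$dropped) - length(pruned$dropped),
    outliers_removed = outl$removed,
    imputation_iterations = iterations,
    imputation_converged = converged,
    listwise = listwise,
    outlier_k = outlier_k), class = "prep_report")
  list(cohort = cohort, specs = specs, report = report)
}

#' @export
print.prep_report <- function(x, ...) {
  cat("<prep_report>\n")
  cat(sprintf("  %d exposures in, %d retained\n", x$n_input, x$n_retained))
  cat(sprintf("  dropped for low endorsement (%d): %s\n",
              length(x$dropped_low_endorsement),
              paste(x$dropped_low_endorsement, collapse = ", ")))
  cat(sprintf("  dropped as collinear (%d): %s\n",
              length(x$dropped_collinear),
              paste(x$dropped_collinear, collapse = ", ")))
  cat(sprintf("  outlier cells removed: %d (k = %s)\n",
              sum(x$outliers_removed), format(x$outlier_k)))
  if (length(x$imputation_iterations))
    cat(sprintf("  imputation sweeps: train %s, test %s\n",
                x$imputation_iterations$train, x$imputation_iterations$test))
  else cat("  imputation skipped (list-wise variant)\n")
  invisible(x)
}

#' Serialize a preparation report as JSON
#'
#' @param report A `prep_report` from [run_prep()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_prep_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
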