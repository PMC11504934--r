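# Covariates offered to the imputation forests, when present and complete.
IMPUTE_COVARIATES <- c("age", "sex", "race_black", "race_white", "hispanic",
                       "sgm", "income_ordinal", "parent_education",
                       "adversity", "nonsocial_screentime")

#' Iterative random-forest imputation of missing exposures
#'
#' Nonparametric single imputation in the style of missForest: missing cells
#' are initialised with the column mean (continuous) or mode
#' (binary/ordinal); variables are then visited in order of increasing
#' missingness, each regressed on all other exposures (plus complete
#' demographic covariates) with a bagged regression forest fitted on its
#' observed rows, and its missing cells replaced by forest predictions.
#' Sweeps repeat until the normalized change in imputed values increases for
#' every variable type present — continuous: ratio of summed squared
#' differences; binary/ordinal: disagreement proportion — or `max_iter` is
#' reached; the iterate preceding the first degradation is returned.
#'
#' Binary predictions are thresholded at 0.5; ordinal predictions are
#' rounded and clamped to the observed level range. Observed cells are never
#' altered, and identifiers and outcome columns never enter the imputation
#' matrix. Train and test subsamples should be imputed in separate calls.
#'
#' @param cohort Cohort `data.frame` (typically one subsample).
#' @param specs `exposure_spec` table naming the exposure columns.
#' @param max_iter Maximum number of sweeps (default 10).
#' @param n_trees Trees per forest (default 100).
#' @param seed Integer seed; identical input and seed give identical output.
#' @param min_node Minimum node size of the forest (default 5).
#' @return List with `cohort` (no missing exposure cells), `iterations`
#'   (sweeps contributing to the returned iterate; 0 when nothing was
#'   missing) and `converged` (`TRUE` when stopped by the degradation rule
#'   rather than `max_iter`).
#' @export
impute_missforest <- function(cohort, specs, max_iter = 10L, n_trees = 100L,
                              seed = 1L, min_node = 5L) {
  vars <- intersect(specs$name, names(cohort))
  if (!length(vars)) stop("no exposure columns found in cohort")
  type <- setNames(specs$measurement[match(vars, specs$name)], vars)

  miss <- vapply(vars, function(v) sum(is.na(cohort[[v]])), integer(1))
  all_missing <- vars[miss == nrow(cohort)]
  if (length(all_missing))
    stop("impute_missforest: no observed values for ",
         paste(all_missing, collapse = ", "))
  if (all(miss == 0L))
    return(list(cohort = cohort, iterations = 0L, converged = TRUE))

  covars <- intersect(IMPUTE_COVARIATES, names(cohort))
  covars <- covars[vapply(covars, function(v) !anyNA(cohort[[v]]), logical(1))]
  Xcov <- NULL
  if (length(covars)) {
    Xcov <- cohort[, covars, drop = FALSE]
    if ("sex" %in% covars) Xcov$sex <- as.numeric(Xcov$sex == "male")
    Xcov <- as.matrix(data.matrix(Xcov))
  }

  orig <- as.matrix(cohort[, vars, drop = FALSE])
  na_mask <- is.na(orig)
  M <- orig
  for (v in vars) {
    j <- match(v, vars)
    if (!any(na_mask[, j])) next
    obs <- orig[!na_mask[, j], j]
    fill <- if (type[v] == "continuous") mean(obs) else mode_value(obs)
    M[na_mask[, j], j] <- fill
  }

  visit <- vars[order(miss[vars], vars)]
  visit <- visit[miss[visit] > 0L]
  is_cont <- type == "continuous"
  cont_cells <- na_mask[, vars[is_cont], drop = FALSE]
  cat_cells <- na_mask[, vars[!is_cont], drop = FALSE]

  prev_M <- M
  best_M <- M
  prev_delta <- c(cont = Inf, cat = Inf)
  iterations <- 0L
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    before <- M
    for (v in visit) {
      j <- match(v, vars)
      pred_cols <- cbind(M[, -j, drop = FALSE], Xcov)
      obs_rows <- !na_mask[, j]
      # classic forest defaults: p/3 for a continuous response, sqrt(p)
      # for a categorical one
      mtry <- if (type[v] == "continuous")
        max(1L, floor(ncol(pred_cols) / 3)) else
        max(1L, floor(sqrt(ncol(pred_cols))))
      yhat <- .rf_regress(pred_cols[obs_rows, , drop = FALSE],
                          orig[obs_rows, j],
                          pred_cols[!obs_rows, , drop = FALSE],
                          as.integer(n_trees), mtry, as.integer(min_node),
                          as.integer(seed) + 1009L * iter + j)
      M[!obs_rows, j] <- cast_prediction(yhat, type[v], orig[obs_rows, j])
    }
    delta <- c(cont = change_continuous(M, before, vars[is_cont], cont_cells),
               cat = change_categorical(M, before, vars[!is_cont], cat_cells))
    present <- !is.na(delta)
    if (iter > 1L && all(delta[present] > prev_delta[present])) {
      converged <- TRUE
      best_M <- before
      break
    }
    best_M <- M
    prev_delta <- delta
    iterations <- iter
  }

  out <- cohort
  for (v in vars) {
    col <- best_M[, v]
    if (is.integer(cohort[[v]])) col <- as.integer(round(col))
    out[[v]] <- col
  }
  list(cohort = out, iterations = iterations, converged = converged)
}

mode_value <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

cast_prediction <- function(yhat, type, observed) {
  switch(type,
    continuous = yhat,
    binary = as.numeric(yhat > 0.5),
    ordinal = pmin(max(observed), pmax(min(observed), round(yhat))))
}

change_continuous <- function(M, before, cols, cells) {
  if (!length(cols) || !any(cells)) return(NA_real_)
  new <- M[, cols, drop = FALSE][cells]
  old <- before[, cols, drop = FALSE][cells]
  denom <- sum(new^2)
  if (denom == 0) return(0)
  sum((new - old)^2) / denom
}

change_categorical <- function(M, before, cols, cells) {
  if (!length(cols) || !any(cells)) return(NA_real_)
  new <- M[, cols, drop = FALSE][cells]
  old <- before[, cols, drop = FALSE][cells]
  mean(new != old)
}
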