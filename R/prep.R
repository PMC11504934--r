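#' Merge split hour/minute screentime items
#'
#' Screentime surveys often record a quantity as separate hour and minute
#' items; analysis uses a single value `hours + minutes/60`. For every spec
#' whose `combine_with` names a minutes variable, the combined value replaces
#' the hours variable and the minutes column is removed. A missing component
#' is treated as 0 when its sibling is present; the result is missing only
#' when both are missing.
#'
#' @param cohort Cohort `data.frame`.
#' @param specs An `exposure_spec` table; rows with non-`NA` `combine_with`
#'   define (hours, minutes) pairs, `name` being the hours item.
#' @return A list with the updated `cohort` and `specs` (minutes rows
#'   removed).
#' @export
combine_hour_minute <- function(cohort, specs) {
  todo <- which(!is.na(specs$combine_with))
  drop_names <- character(0)
  for (i in todo) {
    h <- specs$name[i]; m <- specs$combine_with[i]
    if (!all(c(h, m) %in% names(cohort)))
      stop("combine_hour_minute: missing column ", h, " or ", m)
    hv <- cohort[[h]]; mv <- cohort[[m]]
    if (any(hv < 0, na.rm = TRUE) || any(mv < 0, na.rm = TRUE))
      stop("combine_hour_minute: negative components in ", h, "/", m)
    both_na <- is.na(hv) & is.na(mv)
    comb <- ifelse(is.na(hv), 0, hv) + ifelse(is.na(mv), 0, mv) / 60
    comb[both_na] <- NA_real_
    cohort[[h]] <- comb
    drop_names <- c(drop_names, m)
  }
  if (length(drop_names)) {
    cohort <- cohort[, setdiff(names(cohort), drop_names), drop = FALSE]
    specs <- specs[!(specs$name %in% drop_names), , drop = FALSE]
    specs$combine_with <- NA_character_
  }
  list(cohort = cohort, specs = specs)
}

#' Drop rarely endorsed binary exposures
#'
#' Binary exposures whose endorsement (the proportion of non-missing values
#' equal to 1) is strictly below `threshold` are removed; missingness does
#' not deflate endorsement.
#'
#' @param cohort Cohort `data.frame`.
#' @param specs `exposure_spec` table.
#' @param threshold Endorsement cutoff in (0, 1); default 1%.
#' @return List with updated `cohort`, `specs`, and `dropped` (names).
#' @export
filter_low_endorsement <- function(cohort, specs, threshold = 0.01) {
  stopifnot(threshold > 0, threshold < 1)
  bin <- specs$name[specs$measurement == "binary"]
  bin <- intersect(bin, names(cohort))
  endo <- vapply(bin, function(v) mean(cohort[[v]] == 1, na.rm = TRUE),
                 numeric(1))
  dropped <- bin[!is.nan(endo) & endo < threshold]
  cohort <- cohort[, setdiff(names(cohort), dropped), drop = FALSE]
  specs <- specs[!(specs$name %in% dropped), , drop = FALSE]
  list(cohort = cohort, specs = specs, dropped = dropped)
}

#' Remove extreme upper-tail outliers from continuous exposures
#'
#' Values above `Q3 + k * IQR` are set to missing (to be refilled by the
#' imputer, keeping n constant). Quartiles use the left-continuous inverse
#' empirical distribution function (`type = 1`), so on a small sample the
#' fences are actual observed values. Only continuous variables flagged
#' `outlier_rule_applies` are touched; the rule targets one-sided heavy
#' tails such as follower counts. Set `k = Inf` to reproduce the
#' "no outlier removal" sensitivity variant.
#'
#' @param cohort Cohort `data.frame`.
#' @param specs `exposure_spec` table.
#' @param k Fence multiplier (default 3).
#' @return List with updated `cohort` and `removed`, a named integer vector
#'   of per-variable removal counts.
#' @export
remove_outliers <- function(cohort, specs, k = 3) {
  vars <- specs$name[specs$measurement == "continuous" &
                       specs$outlier_rule_applies]
  vars <- intersect(vars, names(cohort))
  removed <- setNames(integer(length(vars)), vars)
  if (is.infinite(k)) return(list(cohort = cohort, removed = removed))
  for (v in vars) {
    x <- cohort[[v]]
    if (all(is.na(x))) {
      warning("remove_outliers: ", v, " is all-missing; skipped")
      next
    }
    q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 1, names = FALSE)
    fence <- q[2] + k * (q[2] - q[1])
    out <- !is.na(x) & x > fence
    removed[v] <- sum(out)
    x[out] <- NA_real_
    cohort[[v]] <- x
  }
  list(cohort = cohort, removed = removed)
}

#' Greedy collinearity pruning on the training subsample
#'
#' While any exposure pair has `|r| > r_threshold` (Pearson, on
#' pairwise-complete observations of the training subsample), the pair with
#' the largest `|r|` is taken and the member with the larger mean absolute
#' correlation against all remaining exposures is dropped — the published
#' behaviour of mean-correlation-based greedy filters. Ties in the pair
#' choice resolve to the first pair in variable-name order; ties in the
#' member choice drop the alphabetically later name. Pruning decisions are
#' made on training rows only and applied to the whole table, preserving
#' train/test hygiene.
#'
#' @param cohort Cohort `data.frame`; rows with `subsample == "train"` drive
#'   the decisions (all rows if there is no `subsample` column).
#' @param exposures Character vector of exposure column names to consider.
#' @param r_threshold Absolute-correlation threshold (default 0.9; the
#'   pruning criterion is strict `>`).
#' @return List with updated `cohort` and `dropped` (names, in drop order).
#' @export
prune_collinear <- function(cohort, exposures, r_threshold = 0.9) {
  exposures <- intersect(exposures, names(cohort))
  if (length(exposures) < 2L)
    stop("prune_collinear needs at least two exposure variables")
  rows <- if ("subsample" %in% names(cohort))
    cohort$subsample == "train" else rep(TRUE, nrow(cohort))
  X <- as.matrix(cohort[rows, exposures, drop = FALSE])

  sds <- apply(X, 2L, sd, na.rm = TRUE)
  degenerate <- names(sds)[is.na(sds) | sds == 0]
  if (length(degenerate)) {
    warning("prune_collinear: zero-variance variable(s) excluded: ",
            paste(degenerate, collapse = ", "))
    X <- X[, setdiff(colnames(X), degenerate), drop = FALSE]
  }

  dropped <- character(0)
  active <- colnames(X)
  if (length(active) >= 2L) {
    C <- abs(suppressWarnings(cor(X, use = "pairwise.complete.obs")))
    diag(C) <- 0
    C[is.na(C)] <- 0
    repeat {
      mx <- max(C)
      if (mx <= r_threshold) break
      hits <- which(C == mx, arr.ind = TRUE)
      hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
      ord <- order(rownames(C)[hits[, 1]], rownames(C)[hits[, 2]])
      i <- hits[ord[1], 1]; j <- hits[ord[1], 2]
      mean_i <- mean(C[i, -i]); mean_j <- mean(C[j, -j])
      victim <- if (mean_i > mean_j) i
        else if (mean_j > mean_i) j
        # tie: drop the alphabetically later name
        else if (rownames(C)[i] > rownames(C)[j]) i else j
      dropped <- c(dropped, rownames(C)[victim])
      C <- C[-victim, -victim, drop = FALSE]
      if (nrow(C) < 2L) break
    }
  }
  cohort <- cohort[, setdiff(names(cohort), dropped), drop = FALSE]
  list(cohort = cohort, dropped = dropped)
}
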