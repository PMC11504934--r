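# Default ExWAS screening covariates: demographics only. Household income
# and parent education deliberately enter later, in the validation models.
EXWAS_COVARIATES <- c("age", "sex", "race_black", "race_white", "hispanic")

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: with p sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("bh_fdr: p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Exposure-wide mixed-model screen on the training subsample
#'
#' Fits one linear mixed model per exposure — the exposure as the single
#' variable of interest plus the demographic covariates, with random
#' intercepts for family nested within site — and applies
#' Benjamini-Hochberg FDR correction across exactly the tested set.
#' Exposures with positive coefficients are classified as risk factors,
#' negative as protective. Non-converged fits stay in the FDR family (their
#' p-value counts toward m) but are flagged and never significant, which
#' bars them from score construction.
#'
#' When no exposure cell is missing (the imputed pipeline), all models share
#' one model structure and row set, and only the exposure column is swapped
#' between fits; results are identical to independent refits. With missing
#' exposure data (the list-wise-deletion sensitivity variant) each exposure
#' is fitted on its own complete rows.
#'
#' @param train Cohort `data.frame`; rows with `subsample == "train"` are
#'   used when that column is present.
#' @param exposures Character vector of exposure columns to screen.
#' @param outcome Continuous outcome column (default `outcome_continuous`).
#' @param covariates Fixed covariates (default demographics).
#' @param specs Optional `exposure_spec` table supplying the `domain`
#'   column of the result.
#' @param alpha Significance threshold on the q-value (default 0.05).
#' @return An `exwas_result` data frame, one row per exposure in input
#'   order: `exposure`, `beta`, `se`, `ci_low`, `ci_high`, `t`, `p`, `q`,
#'   `direction`, `significant`, `converged`, `domain`, `n_used`; run-log
#'   metadata in `attr(, "run_log")`.
#' @export
run_exwas <- function(train, exposures,
                      outcome = "outcome_continuous",
                      covariates = EXWAS_COVARIATES,
                      specs = NULL, alpha = 0.05) {
  if ("subsample" %in% names(train))
    train <- train[train$subsample == "train", , drop = FALSE]
  miss <- setdiff(c(exposures, outcome, covariates), names(train))
  if (length(miss)) stop("run_exwas: missing column(s): ",
                         paste(miss, collapse = ", "))

  base_cols <- c(outcome, covariates, "site_id", "family_id")
  rows <- stats::complete.cases(train[, base_cols, drop = FALSE])
  d <- train[rows, , drop = FALSE]
  fast <- !anyNA(d[, exposures, drop = FALSE])

  fits <- vector("list", length(exposures))
  if (fast) {
    d$.exposure <- d[[exposures[1]]]  # placeholder with real variation
    lf <- build_lformula(d, outcome, c(".exposure", covariates),
                         "site_id", "family_id")
    for (k in seq_along(exposures)) {
      v <- exposures[k]
      lf$X[, ".exposure"] <- d[[v]]
      lf$fr$.exposure <- d[[v]]
      fits[[k]] <- lmm_fit_from_lf(lf, quiet = TRUE,
                                   term_rename = c(".exposure", v))
    }
  } else {
    for (k in seq_along(exposures))
      fits[[k]] <- fit_lmm(train, outcome, c(exposures[k], covariates),
                           quiet = TRUE)
  }

  rec <- do.call(rbind, lapply(seq_along(exposures), function(k) {
    b <- fits[[k]]$beta
    row <- b[b$term == exposures[k], , drop = FALSE]
    data.frame(exposure = exposures[k], beta = row$estimate, se = row$se,
               ci_low = row$ci_low, ci_high = row$ci_high, t = row$t,
               p = row$p, converged = fits[[k]]$converged,
               n_used = fits[[k]]$n_used, stringsAsFactors = FALSE)
  }))
  rec$q <- bh_fdr(rec$p)
  rec$direction <- ifelse(rec$beta > 0, "risk", "protective")
  rec$significant <- rec$q < alpha & rec$converged
  rec$domain <- if (!is.null(specs))
    specs$domain[match(rec$exposure, specs$name)] else NA_character_
  rec <- rec[, c("exposure", "beta", "se", "ci_low", "ci_high", "t", "p",
                 "q", "direction", "significant", "converged", "domain",
                 "n_used")]
  attr(rec, "run_log") <- list(
    n_tested = nrow(rec),
    n_converged = sum(rec$converged),
    n_significant = sum(rec$significant),
    alpha = alpha, outcome = outcome, covariates = covariates,
    n_rows = sum(rows), fast_path = fast)
  class(rec) <- c("exwas_result", "data.frame")
  rec
}

#' @export
print.exwas_result <- function(x, digits = 3, ...) {
  log <- attr(x, "run_log")
  cat(sprintf("<exwas_result> %d exposures screened, %d significant (q < %s)\n",
              nrow(x), sum(x$significant),
              format(log$alpha %||% 0.05)))
  print(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}
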