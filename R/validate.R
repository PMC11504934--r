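# Demographic covariates of the validation models (Model-1 set): income and
# parent education join the demographics here, unlike the screening stage.
VALIDATION_COVARIATES <- c("age", "sex", "race_black", "race_white",
                           "hispanic", "income_ordinal", "parent_education")

# Merge z-scores into the testing rows and attach a z-scored non-social
# screentime column. Standardization happens before any model-specific
# list-wise deletion.
merge_scores <- function(test, scores, screentime_col = "nonsocial_screentime") {
  if ("subsample" %in% names(test) && any(test$subsample == "test"))
    test <- test[test$subsample == "test", , drop = FALSE]
  test$score_z <- scores$z_score[match(test$participant_id,
                                       scores$participant_id)]
  st <- test[[screentime_col]]
  test$screentime_z <- as.numeric((st - mean(st, na.rm = TRUE)) /
                                    sd(st, na.rm = TRUE))
  test
}

#' Nested mixed-model validation of the exposomic risk score
#'
#' Fits the four-model sequence on the testing subsample: demographics
#' (Model-1), plus non-social screentime (Model-2), plus non-digital
#' childhood adversity (Model-3), plus the digital exposomic risk score
#' (Model-4). All four models share one row set — rows missing the outcome
#' or any Model-4 variable are list-wise deleted up front, so marginal-R2
#' comparisons are well defined — and the same family-within-site random
#' intercepts.
#'
#' @param test Cohort `data.frame` (testing subsample rows are used).
#' @param scores A `score_vector` from [compute_scores()].
#' @param outcome Continuous outcome column.
#' @param adversity_col Non-digital adversity column.
#' @param screentime_col Non-social screentime column (z-scored internally).
#' @return A `nested_report`: `fits` (named list M1-M4 of `lmm_fit`),
#'   `table` (model, marginal_r2, delta_r2, n_used), `converged`.
#' @export
run_nested_validation <- function(test, scores,
                                  outcome = "outcome_continuous",
                                  adversity_col = "adversity",
                                  screentime_col = "nonsocial_screentime") {
  d <- merge_scores(test, scores, screentime_col)
  term_sets <- list(
    M1 = VALIDATION_COVARIATES,
    M2 = c(VALIDATION_COVARIATES, "screentime_z"),
    M3 = c(VALIDATION_COVARIATES, "screentime_z", adversity_col),
    M4 = c(VALIDATION_COVARIATES, "screentime_z", adversity_col, "score_z"))
  keep <- stats::complete.cases(
    d[, c(outcome, term_sets$M4, "site_id", "family_id"), drop = FALSE])
  d <- d[keep, , drop = FALSE]

  fits <- lapply(term_sets, function(tt) fit_lmm(d, outcome, tt, quiet = TRUE))
  r2 <- vapply(fits, marginal_r2, numeric(1))
  converged <- all(vapply(fits, `[[`, logical(1), "converged"))
  delta <- c(r2[1], diff(r2))
  if (!converged) delta <- rep(NA_real_, 4L)
  tab <- data.frame(model = names(term_sets),
                    marginal_r2 = unname(r2),
                    delta_r2 = unname(delta),
                    n_used = vapply(fits, `[[`, integer(1), "n_used"),
                    stringsAsFactors = FALSE)
  structure(list(fits = fits, table = tab, converged = converged),
            class = "nested_report")
}

#' @export
print.nested_report <- function(x, digits = 4, ...) {
  cat("<nested_report>", if (!x$converged) "(non-converged fit: delta R2 suppressed)",
      "\n")
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Logistic models for the rare binary outcome
#'
#' Mirrors the nested sequence with a lifetime suicide-attempt analog as
#' outcome: the exposomic score (per 1 SD) plus demographics and non-social
#' screentime, and the same model additionally adjusted for non-digital
#' adversity. Both fits use the rows complete for the larger model.
#'
#' @param test Cohort `data.frame` (testing subsample rows are used).
#' @param scores A `score_vector`.
#' @param outcome Binary outcome column.
#' @param adversity_col,screentime_col Covariate columns.
#' @return Named list of two `glm_fit`s: `score_demo_screentime`,
#'   `plus_adversity`.
#' @export
run_attempt_models <- function(test, scores,
                               outcome = "outcome_binary",
                               adversity_col = "adversity",
                               screentime_col = "nonsocial_screentime") {
  d <- merge_scores(test, scores, screentime_col)
  terms_small <- c("score_z", VALIDATION_COVARIATES, "screentime_z")
  terms_big <- c(terms_small, adversity_col)
  keep <- stats::complete.cases(d[, c(outcome, terms_big), drop = FALSE])
  d <- d[keep, , drop = FALSE]
  if (sum(d[[outcome]], na.rm = TRUE) == 0L)
    stop("run_attempt_models: outcome all zero after deletion")
  list(score_demo_screentime = fit_logistic(d, outcome, terms_small),
       plus_adversity = fit_logistic(d, outcome, terms_big))
}

#' Binarize a continuous outcome at its top decile
#'
#' Flags values strictly above the empirical 90th percentile; ties at the
#' cutoff go to the reference class, so heavy ties can only lower the
#' realized prevalence below 10%.
#'
#' @param x Numeric vector with at least 10 non-missing values.
#' @return Integer 0/1 vector (missing preserved) with attributes `cutoff`
#'   and `prevalence` (realized, among non-missing).
#' @export
binarize_top_decile <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 10L) stop("binarize_top_decile needs >= 10 non-missing values")
  if (min(x[ok]) == max(x[ok])) stop("binarize_top_decile: constant vector")
  cutoff <- quantile(x[ok], 0.9, names = FALSE, type = 7)
  out <- ifelse(ok, as.integer(x > cutoff), NA_integer_)
  attr(out, "cutoff") <- cutoff
  attr(out, "prevalence") <- mean(out[ok])
  out
}

#' E-value for unmeasured confounding
#'
#' The minimum strength of association, on the risk-ratio scale, that an
#' unmeasured confounder would need with both exposure and outcome to
#' explain away an observed association. For a rare outcome (prevalence
#' under roughly 15%) the odds ratio approximates the risk ratio and is
#' used directly; otherwise the square-root correction `RR = sqrt(OR)` is
#' applied. For `RR >= 1`, `E = RR + sqrt(RR * (RR - 1))`; estimates below
#' 1 are inverted first. The confidence-limit E-value uses the limit closer
#' to 1 and is 1 when the interval crosses 1.
#'
#' @param or_point Observed odds ratio (> 0).
#' @param ci_low,ci_high Optional 95% confidence limits.
#' @param rare_outcome Treat the odds ratio as a risk ratio (default TRUE).
#' @return An `evalue_result`: `observed_or`, `ci_limit`, `evalue_point`,
#'   `evalue_ci` (NA when no limit given).
#' @export
#' @examples
#' evalue(1.95, ci_low = 1.73, ci_high = 2.20)  # E = 3.3 (CI 2.9)
evalue <- function(or_point, ci_low = NA_real_, ci_high = NA_real_,
                   rare_outcome = TRUE) {
  if (!is.finite(or_point) || or_point <= 0)
    stop("evalue: or_point must be positive")
  if ((is.finite(ci_low) && ci_low <= 0) || (is.finite(ci_high) && ci_high <= 0))
    stop("evalue: confidence limits must be positive")
  to_rr <- function(or) if (rare_outcome) or else sqrt(or)
  e_of <- function(rr) {
    if (rr < 1) rr <- 1 / rr
    rr + sqrt(rr * (rr - 1))
  }
  point <- e_of(to_rr(or_point))

  ci_limit <- NA_real_
  e_ci <- NA_real_
  have <- c(low = is.finite(ci_low), high = is.finite(ci_high))
  if (any(have)) {
    if (all(have) && ci_low < 1 && ci_high > 1) {
      e_ci <- 1
      ci_limit <- if (abs(log(ci_low)) < abs(log(ci_high))) ci_low else ci_high
    } else {
      cand <- c(ci_low, ci_high)[c(have["low"], have["high"])]
      ci_limit <- cand[which.min(abs(log(cand)))]
      e_ci <- if ((ci_limit < 1) != (or_point < 1) ||
                  isTRUE(all.equal(ci_limit, 1))) 1 else e_of(to_rr(ci_limit))
    }
  }
  structure(list(observed_or = or_point, ci_limit = ci_limit,
                 evalue_point = point, evalue_ci = e_ci,
                 rare_outcome = rare_outcome),
            class = "evalue_result")
}

#' @export
print.evalue_result <- function(x, ...) {
  cat(sprintf("<evalue_result> OR = %.3f -> E = %.2f", x$observed_or,
              x$evalue_point))
  if (is.finite(x$evalue_ci))
    cat(sprintf(" (CI limit %.3f -> E = %.2f)", x$ci_limit, x$evalue_ci))
  cat("\n")
  invisible(x)
}

#' Top-decile E-value sensitivity analysis for the main validation model
#'
#' Binarizes the continuous outcome at its top decile, fits a logistic
#' model with all Model-4 covariates (score, demographics, non-social
#' screentime, adversity), and converts the score's odds ratio and its
#' near-1 confidence limit to E-values treating the odds ratio as a risk
#' ratio (the binarized outcome is rare at 10%).
#'
#' @inheritParams run_nested_validation
#' @return An `evalue_result` with additional fields `outcome_cutoff` and
#'   `prevalence`.
#' @export
run_evalue_analysis <- function(test, scores,
                                outcome = "outcome_continuous",
                                adversity_col = "adversity",
                                screentime_col = "nonsocial_screentime") {
  d <- merge_scores(test, scores, screentime_col)
  terms <- c("score_z", VALIDATION_COVARIATES, "screentime_z", adversity_col)
  keep <- stats::complete.cases(d[, c(outcome, terms), drop = FALSE])
  d <- d[keep, , drop = FALSE]
  hi <- binarize_top_decile(d[[outcome]])
  d$.high_outcome <- as.integer(hi)
  fit <- fit_logistic(d, ".high_outcome", terms)
  row <- fit$or[fit$or$term == "score_z", ]
  res <- evalue(row$odds_ratio, row$ci_low, row$ci_high, rare_outcome = TRUE)
  res$outcome_cutoff <- attr(hi, "cutoff")
  res$prevalence <- attr(hi, "prevalence")
  res
}
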