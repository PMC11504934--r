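#' Logistic regression with odds ratios and Wald intervals
#'
#' Maximum-likelihood logistic fit after list-wise deletion, reporting
#' exponentiated coefficients with Wald 95% confidence intervals. Site and
#' family clustering are not modelled here (plain logistic regression is
#' the convention for the rare binary outcome); treat clustered standard
#' errors as a known limitation.
#'
#' @param data Cohort `data.frame`.
#' @param outcome Name of the 0/1 outcome column.
#' @param fixed_terms Character vector of predictor column names.
#' @return An object of class `glm_fit`: `or` (term, odds_ratio, ci_low,
#'   ci_high, z, p), `coef` (log-odds scale: term, estimate, se), `n_used`,
#'   `converged`.
#' @export
fit_logistic <- function(data, outcome, fixed_terms) {
  cols <- c(outcome, fixed_terms)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("fit_logistic: missing column(s): ",
                         paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  y <- d[[outcome]]
  if (length(unique(y)) < 2L)
    stop("fit_logistic: outcome has a single class after list-wise deletion")
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  fml <- as.formula(paste(outcome, "~", rhs))
  fit <- suppressWarnings(glm(fml, data = d, family = binomial()))

  est <- coef(fit)
  est <- est[!is.na(est)]  # aliased terms dropped
  se <- sqrt(diag(vcov(fit)))[names(est)]
  big <- abs(est) > 12
  if (any(big[-1] & se[-1] > 50))
    stop("fit_logistic: complete separation suspected for term: ",
         paste(names(est)[-1][big[-1] & se[-1] > 50], collapse = ", "))
  z <- est / se
  or_tab <- data.frame(term = names(est),
                       odds_ratio = unname(exp(est)),
                       ci_low = unname(exp(est - 1.96 * se)),
                       ci_high = unname(exp(est + 1.96 * se)),
                       z = unname(z),
                       p = unname(2 * pnorm(-abs(z))),
                       stringsAsFactors = FALSE)
  structure(list(or = or_tab,
                 coef = data.frame(term = names(est),
                                   estimate = unname(est), se = unname(se),
                                   stringsAsFactors = FALSE),
                 n_used = nrow(d),
                 converged = isTRUE(fit$converged)),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<glm_fit> n = %d, %sconverged\n", x$n_used,
              if (x$converged) "" else "NOT "))
  print(format(x$or, digits = digits), row.names = FALSE)
  invisible(x)
}
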