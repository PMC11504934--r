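lmm_control <- function() {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.singular = "ignore",
                    check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    check.nobs.vs.rankZ = "ignore",
                    check.nlev.gtreq.5 = "ignore")
}

#' Fit the two-level random-intercept linear mixed model
#'
#' REML fit of `outcome ~ fixed_terms + (1 | site) + (1 | site:family)`,
#' i.e. random intercepts for family nested within study site, after
#' list-wise deletion of rows missing the outcome or any fixed term.
#' Fixed-effect p-values use the large-sample normal reference for
#' `t = estimate/se`, and 95% confidence intervals are Wald
#' (`estimate +/- 1.96 se`): with thousands of clusters the difference from
#' finite-df corrections is negligible. Variance components are bounded at
#' zero; a singular fit reports the component as 0 (with a warning unless
#' `quiet = TRUE`).
#'
#' @param data Cohort `data.frame`.
#' @param outcome Name of the continuous outcome column.
#' @param fixed_terms Character vector of fixed-effect column names.
#' @param site_col,family_col Grouping identifier columns.
#' @param quiet Suppress singular-fit warnings (useful in screening loops).
#' @return An object of class `lmm_fit`: `beta` (term, estimate, se, ci_low,
#'   ci_high, t, p), `var_family_in_site`, `var_site`, `var_resid`,
#'   `fixed_var` (sample variance of the fixed-effect linear predictor),
#'   `marginal_r2`, `icc`, `n_used`, `converged`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_families = 200, n_exposures = 4,
#'                                   n_true_risk = 1, n_true_protective = 0,
#'                                   n_rare = 0, n_collinear_pairs = 0,
#'                                   missing_rate = 0, seed = 5))
#' f <- fit_lmm(sim$cohort, "outcome_continuous", c("age", "adversity"))
#' f$icc
fit_lmm <- function(data, outcome, fixed_terms,
                    site_col = "site_id", family_col = "family_id",
                    quiet = FALSE) {
  cols <- c(outcome, fixed_terms, site_col, family_col)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("fit_lmm: missing column(s): ",
                         paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, cols]), cols, drop = FALSE]
  if (length(unique(d[[site_col]])) < 2L)
    stop("fit_lmm needs at least two sites after list-wise deletion")
  lf <- build_lformula(d, outcome, fixed_terms, site_col, family_col)
  lmm_fit_from_lf(lf, quiet = quiet)
}

build_lformula <- function(d, outcome, fixed_terms, site_col, family_col) {
  rhs <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ") else "1"
  fml <- as.formula(sprintf("%s ~ %s + (1 | %s) + (1 | %s:%s)",
                            outcome, rhs, site_col, site_col, family_col))
  lme4::lFormula(fml, data = d, REML = TRUE, control = lmm_control())
}

# Optimize a prepared lFormula structure and assemble an lmm_fit. Shared by
# fit_lmm and the ExWAS loop (which reuses the structure, swapping one fixed
# column), so a screening record is bit-identical to a stand-alone refit.
lmm_fit_from_lf <- function(lf, quiet = FALSE, term_rename = NULL) {
  devfun <- do.call(lme4::mkLmerDevfun, lf)
  opt <- lme4::optimizeLmer(devfun, optimizer = "nloptwrap")
  m <- lme4::mkMerMod(environment(devfun), opt, lf$reTrms, fr = lf$fr)

  est <- lme4::fixef(m)
  se <- sqrt(diag(as.matrix(vcov(m))))
  terms <- names(est)
  if (!is.null(term_rename))
    terms[terms == term_rename[1]] <- term_rename[2]
  tval <- est / se
  beta <- data.frame(term = terms, estimate = unname(est), se = unname(se),
                     ci_low = unname(est - 1.96 * se),
                     ci_high = unname(est + 1.96 * se),
                     t = unname(tval),
                     p = unname(2 * pnorm(-abs(tval))),
                     stringsAsFactors = FALSE)

  vc <- as.data.frame(lme4::VarCorr(m))
  grp <- vc$grp
  fam_row <- grep(":", grp)
  site_row <- setdiff(which(grp != "Residual"), fam_row)
  var_family <- if (length(fam_row)) vc$vcov[fam_row[1]] else 0
  var_site <- if (length(site_row)) vc$vcov[site_row[1]] else 0
  var_resid <- vc$vcov[grp == "Residual"]
  singular <- min(var_family, var_site) < 1e-10 * var_resid
  if (singular && !quiet)
    warning("singular fit: a variance component is estimated as 0")

  fixed_var <- as.numeric(var(as.vector(lf$X %*% est)))
  total <- fixed_var + var_family + var_site + var_resid
  converged <- is.null(opt$conv) || opt$conv == 0L

  structure(list(beta = beta,
                 var_family_in_site = var_family,
                 var_site = var_site,
                 var_resid = var_resid,
                 fixed_var = fixed_var,
                 marginal_r2 = fixed_var / total,
                 icc = (var_family + var_site) /
                   (var_family + var_site + var_resid),
                 n_used = nrow(lf$fr),
                 converged = converged,
                 reml_criterion = as.numeric(opt$fval)),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<lmm_fit> n = %d, %sconverged\n", x$n_used,
              if (x$converged) "" else "NOT "))
  print(format(x$beta, digits = digits), row.names = FALSE)
  cat(sprintf("variance components: family:site %.3f, site %.3f, residual %.3f\n",
              x$var_family_in_site, x$var_site, x$var_resid))
  cat(sprintf("marginal R2 = %.4f, ICC = %.3f\n", x$marginal_r2, x$icc))
  invisible(x)
}

#' Nakagawa marginal R-squared of a mixed-model fit
#'
#' The fraction of outcome variance attributable to the fixed effects:
#' `s2_fixed / (s2_fixed + var_family_in_site + var_site + var_resid)`,
#' where `s2_fixed` is the sample variance of the fixed-effects linear
#' predictor.
#'
#' @param fit An `lmm_fit`.
#' @param fixed_predictor_variance Sample variance of the fixed-effect
#'   linear predictor; defaults to the value recorded in `fit`.
#' @return A number in \[0, 1\].
#' @export
marginal_r2 <- function(fit, fixed_predictor_variance = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  fv <- fixed_predictor_variance %||% fit$fixed_var
  total <- fv + fit$var_family_in_site + fit$var_site + fit$var_resid
  if (total <= 0) stop("marginal_r2 undefined: all variances are zero")
  fv / total
}

#' Intra-class correlation of a mixed-model fit
#'
#' Share of total variance due to clustering:
#' `(var_family_in_site + var_site) / (var_family_in_site + var_site +
#' var_resid)`.
#'
#' @param var_family_in_site,var_site,var_resid Variance components; or pass
#'   an `lmm_fit` as the first argument.
#' @return A number in \[0, 1\].
#' @export
icc <- function(var_family_in_site, var_site = NULL, var_resid = NULL) {
  if (inherits(var_family_in_site, "lmm_fit")) {
    f <- var_family_in_site
    var_family_in_site <- f$var_family_in_site
    var_site <- f$var_site
    var_resid <- f$var_resid
  }
  (var_family_in_site + var_site) /
    (var_family_in_site + var_site + var_resid)
}
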