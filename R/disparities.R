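rank_tie_term <- function(r) {
  t <- table(r)
  sum(t^3 - t)
}

group_levels <- function(g) {
  if (is.factor(g)) levels(droplevels(g)) else unique(g[!is.na(g)])
}

#' Kruskal-Wallis test across three or more groups
#'
#' Rank-based H statistic with tie correction, referred to a chi-squared
#' distribution with k - 1 degrees of freedom.
#'
#' @param x Numeric vector (e.g., exposomic risk z-scores).
#' @param g Group labels (>= 3 levels, each with n >= 2).
#' @return A `group_test` list: `test`, `groups`, `statistic` (H), `df`,
#'   `p`, `medians`, `n`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
#'                rep(c("a", "b", "c"), each = 3))
kruskal_wallis <- function(x, g) {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]
  lev <- group_levels(g[ok])
  g <- as.character(g[ok])
  if (length(lev) < 3L)
    stop("kruskal_wallis needs >= 3 groups; use mann_whitney_rb for 2")
  n_g <- table(g)[lev]
  if (any(n_g < 2L)) stop("kruskal_wallis: every group needs n >= 2")
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)[lev]
  H <- 12 / (N * (N + 1)) * sum(n_g * (rbar - (N + 1) / 2)^2)
  correction <- 1 - rank_tie_term(x) / (N^3 - N)
  H <- H / correction
  structure(list(test = "kruskal_wallis", groups = lev,
                 statistic = unname(H), df = length(lev) - 1L,
                 p = pchisq(H, length(lev) - 1L, lower.tail = FALSE),
                 medians = tapply(x, g, median)[lev],
                 n = as.integer(n_g)),
            class = "group_test")
}

#' Dunn's pairwise comparisons with Holm adjustment
#'
#' Post-hoc pairwise z tests on the pooled ranking after a Kruskal-Wallis
#' test: `z = (mean-rank difference) / sqrt((N(N+1)/12 - tie_term /
#' (12(N-1))) (1/n_i + 1/n_j))`, with Holm step-down adjustment over all
#' pairs.
#'
#' @inheritParams kruskal_wallis
#' @return A `data.frame` of class `dunn_result`: `group1`, `group2`,
#'   `mean_rank_1`, `mean_rank_2`, `z`, `p`, `p_adj`.
#' @export
dunn_holm <- function(x, g) {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]
  lev <- group_levels(g[ok])
  g <- as.character(g[ok])
  if (length(lev) < 3L)
    stop("dunn_holm needs >= 3 groups; use mann_whitney_rb for 2")
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)[lev]
  n_g <- table(g)[lev]
  tie <- rank_tie_term(x)
  pairs <- utils::combn(lev, 2L)
  res <- apply(pairs, 2L, function(pp) {
    i <- pp[1]; j <- pp[2]
    se <- sqrt((N * (N + 1) / 12 - tie / (12 * (N - 1))) *
                 (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    mean_rank_1 = unname(rbar[pairs[1, ]]),
                    mean_rank_2 = unname(rbar[pairs[2, ]]),
                    z = res["z", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adj <- holm_adjust(out$p)
  class(out) <- c("dunn_result", "data.frame")
  out
}

#' Holm step-down p-value adjustment
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in input order, monotone along the Holm
#'   ordering and never below the input.
#' @export
holm_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("holm_adjust: p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- cummax(pmin(1, (m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Mann-Whitney test with rank-biserial effect size
#'
#' Two-group rank test using the tie-corrected normal approximation
#' (no continuity correction), with the Glass rank-biserial coefficient
#' `r = 2 U1 / (n1 n2) - 1`, where `U1` counts wins of the first-listed
#' group; positive values mean the first-listed group tends larger.
#'
#' @param x Numeric vector.
#' @param g Two-group labels; the first factor level (or first value
#'   encountered) is the first-listed group.
#' @return A `group_test` list with `statistic` (U of the first-listed
#'   group), `p`, `effect_size`, `medians`, `n`.
#' @export
mann_whitney_rb <- function(x, g) {
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]
  lev <- group_levels(g[ok])
  g <- as.character(g[ok])
  if (length(lev) != 2L) stop("mann_whitney_rb needs exactly 2 groups")
  n1 <- sum(g == lev[1]); n2 <- sum(g == lev[2])
  if (n1 == 0L || n2 == 0L) stop("mann_whitney_rb: empty group")
  N <- n1 + n2
  r <- rank(x)
  U1 <- sum(r[g == lev[1]]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 * ((N + 1) - rank_tie_term(x) / (N * (N - 1)))
  z <- if (sig2 > 0) (U1 - mu) / sqrt(sig2) else 0
  structure(list(test = "mann_whitney", groups = lev,
                 statistic = unname(U1), df = NULL,
                 p = 2 * pnorm(-abs(z)),
                 effect_size = unname(2 * U1 / (n1 * n2) - 1),
                 medians = tapply(x, g, median)[lev],
                 n = c(n1, n2)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s over %s\n", x$test,
              paste(x$groups, collapse = ", ")))
  cat(sprintf("  statistic = %.4f%s, p = %.3g\n", x$statistic,
              if (!is.null(x$df)) sprintf(" (df = %d)", x$df) else "",
              x$p))
  if (!is.null(x$effect_size))
    cat(sprintf("  rank-biserial r = %.3f\n", x$effect_size))
  cat("  medians:", paste(sprintf("%s = %.3g", names(x$medians), x$medians),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Three-level race/ethnicity grouping
#'
#' Mutually exclusive labels: `hispanic` (any Hispanic ethnicity),
#' `nh_black`, `nh_white`; all other combinations are `NA` and excluded
#' from the three-group disparity tests.
#'
#' @param cohort Cohort `data.frame` with `race_black`, `race_white`,
#'   `hispanic` indicator columns.
#' @return Character vector aligned with `cohort` rows.
#' @export
derive_race3 <- function(cohort) {
  out <- rep(NA_character_, nrow(cohort))
  out[cohort$hispanic == 1] <- "hispanic"
  out[cohort$hispanic == 0 & cohort$race_black == 1] <- "nh_black"
  out[cohort$hispanic == 0 & cohort$race_black == 0 &
        cohort$race_white == 1] <- "nh_white"
  out
}

#' Score-by-group interaction and stratified simple slopes
#'
#' Augments the main validation model (Model-4 covariates) with
#' score-by-group product terms and, separately, refits Model-4 within each
#' group level to obtain stratified simple slopes of the exposomic score. A
#' significant interaction indicates the score-outcome association differs
#' across the groups (differential effects). Supported groupings: `"sex"`
#' (male indicator interaction), `"race3"` (Black and Hispanic indicator
#' interactions against non-Hispanic White), or any 0/1 column such as
#' `"sgm"` (indicator main effect added if absent from the base model).
#'
#' @inheritParams run_nested_validation
#' @param group `"sex"`, `"race3"`, or the name of a 0/1 column.
#' @return An `interaction_result`: `terms` (interaction rows of the
#'   augmented fit), `stratified` (per-level slope, CI, n, low-n flag) and
#'   `fit` (the augmented `lmm_fit`).
#' @export
fit_interactions <- function(test, scores, group,
                             outcome = "outcome_continuous",
                             adversity_col = "adversity",
                             screentime_col = "nonsocial_screentime") {
  d <- merge_scores(test, scores, screentime_col)
  base_terms <- c(VALIDATION_COVARIATES, "screentime_z", adversity_col,
                  "score_z")
  if (group == "sex") {
    d$.sex_male <- as.numeric(d$sex == "male")
    prods <- ".score_x_sex_male"
    d$.score_x_sex_male <- d$score_z * d$.sex_male
    extra_main <- character(0)
    strata <- list(female = d$sex == "female", male = d$sex == "male")
  } else if (group == "race3") {
    r3 <- derive_race3(d)
    prods <- c(".score_x_black", ".score_x_hispanic")
    d$.score_x_black <- d$score_z * d$race_black
    d$.score_x_hispanic <- d$score_z * d$hispanic
    extra_main <- character(0)
    strata <- lapply(c(nh_white = "nh_white", nh_black = "nh_black",
                       hispanic = "hispanic"),
                     function(l) !is.na(r3) & r3 == l)
  } else {
    if (!group %in% names(d)) stop("fit_interactions: unknown group ", group)
    if (!all(d[[group]] %in% c(0, 1, NA)))
      stop("fit_interactions: ", group, " must be a 0/1 column")
    prods <- paste0(".score_x_", group)
    d[[prods]] <- d$score_z * d[[group]]
    extra_main <- setdiff(group, base_terms)
    strata <- setNames(list(d[[group]] == 0, d[[group]] == 1),
                       paste0(group, c("_0", "_1")))
  }

  fit <- fit_lmm(d, outcome, c(base_terms, extra_main, prods), quiet = TRUE)
  terms_tab <- fit$beta[fit$beta$term %in% prods, , drop = FALSE]

  strat <- do.call(rbind, lapply(names(strata), function(nm) {
    rows <- strata[[nm]] & !is.na(strata[[nm]])
    sub <- d[rows, , drop = FALSE]
    n_lvl <- nrow(sub)
    if (n_lvl < 50L || length(unique(sub$site_id)) < 2L)
      return(data.frame(group = nm, estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n = n_lvl, low_n = TRUE,
                        stringsAsFactors = FALSE))
    # covariates constant within the stratum (e.g. the stratifier itself)
    # drop out of the stratified model
    keep_terms <- base_terms[vapply(base_terms, function(tt)
      length(unique(sub[[tt]][!is.na(sub[[tt]])])) > 1L, logical(1))]
    f <- fit_lmm(sub, outcome, keep_terms, quiet = TRUE)
    b <- f$beta[f$beta$term == "score_z", ]
    data.frame(group = nm, estimate = b$estimate, ci_low = b$ci_low,
               ci_high = b$ci_high, n = f$n_used, low_n = FALSE,
               stringsAsFactors = FALSE)
  }))
  structure(list(terms = terms_tab, stratified = strat, fit = fit),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, digits = 3, ...) {
  cat("<interaction_result>\n")
  print(format(x$terms, digits = digits), row.names = FALSE)
  cat("stratified simple slopes:\n")
  print(format(x$stratified, digits = digits), row.names = FALSE)
  invisible(x)
}
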