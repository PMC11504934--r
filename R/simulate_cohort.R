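# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Ordinal exposures take levels 0..4 with these standard-normal cutpoints.
ORDINAL_CUTS <- qnorm(c(0.35, 0.65, 0.85, 0.95))
ORDINAL_LEVELS <- 0:4

ordinal_sd0 <- function() {
  p <- diff(c(0, pnorm(ORDINAL_CUTS), 1))
  m <- sum(ORDINAL_LEVELS * p)
  sqrt(sum(ORDINAL_LEVELS^2 * p) - m^2)
}

#' Simulate a clustered digital-exposome cohort with known ground truth
#'
#' Generates one row per child with identifiers (site, family, participant),
#' demographic covariates, a panel of correlated binary/ordinal/continuous
#' digital exposures (including planted rare and near-collinear variables),
#' a continuous outcome built from configured true exposure effects plus
#' family-within-site and site random intercepts, a rare binary outcome
#' sharing the same exposure burden, exposure-only missingness, and a
#' family-integral train/test split. The companion `truth` object records
#' everything a recovery test needs.
#'
#' All exposures load on one latent "exposure burden" factor, which is what
#' produces realistic inter-exposure correlation and the configured subgroup
#' differences in burden.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional integer overriding `config$seed`.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{cohort}{`data.frame`, one row per participant (see Details).}
#'     \item{truth}{`sim_truth` object: `true_beta` (per raw exposure unit),
#'       `beta_std` (per exposure SD), `null_set`, `collinear_pairs`,
#'       `rare_set`, `variance_components`, `subgroup_shifts`,
#'       `latent_burden` (named per-participant true weighted burden,
#'       computed on complete pre-missingness data), `exposure_meta`,
#'       `binary_intercept`.}
#'   }
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_families = 150, n_exposures = 10,
#'                                   n_true_risk = 3, n_true_protective = 1,
#'                                   n_rare = 1, n_collinear_pairs = 1,
#'                                   seed = 42))
#' table(sim$cohort$subsample)
simulate_cohort <- function(config, seed = NULL) {
  config <- validate_sim_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  ## --- structure: sites, families, children -------------------------------
  fam_site <- sample(rep_len(seq_len(cfg$n_sites), cfg$n_families))
  kids <- 1L + rpois(cfg$n_families, cfg$mean_children_per_family - 1)
  n <- sum(kids)
  fam_of_child <- rep(seq_len(cfg$n_families), kids)
  site_of_child <- fam_site[fam_of_child]

  site_id <- sprintf("S%02d", site_of_child)
  family_id <- sprintf("F%05d", fam_of_child)
  participant_id <- sprintf("P%05d", seq_len(n))

  ## --- family-level covariates --------------------------------------------
  race_cat <- sample(c("nh_white", "nh_black", "hispanic", "other"),
                     cfg$n_families, replace = TRUE,
                     prob = c(0.58, 0.19, 0.20, 0.03))
  hisp_white <- race_cat == "hispanic" & runif(cfg$n_families) < 0.5
  f_race_black <- as.integer(race_cat == "nh_black")
  f_race_white <- as.integer(race_cat == "nh_white" | hisp_white)
  f_hispanic <- as.integer(race_cat == "hispanic")
  f_income <- pmin(10L, pmax(1L, as.integer(round(rnorm(cfg$n_families, 6.5, 2)))))
  f_educ <- rnorm(cfg$n_families, 15, 2)
  f_adv <- as.numeric(scale(-0.35 * f_income + rnorm(cfg$n_families)))

  race_black <- f_race_black[fam_of_child]
  race_white <- f_race_white[fam_of_child]
  hispanic <- f_hispanic[fam_of_child]
  income_ordinal <- f_income[fam_of_child]
  parent_education <- f_educ[fam_of_child]
  adversity <- f_adv[fam_of_child]

  ## --- child-level covariates ---------------------------------------------
  age <- rnorm(n, 12.0, 0.66)
  sex <- ifelse(runif(n) < 0.48, "female", "male")
  sgm <- rbinom(n, 1L, 0.08)
  nonsocial_screentime <- pmax(0, rnorm(n, 25, 14))

  ## --- latent exposure burden with subgroup shifts ------------------------
  sh <- cfg$subgroup_exposure_shift
  sh_of <- function(key) if (key %in% names(sh)) sh[[key]] else 0
  shift <- sh_of("race_black") * race_black + sh_of("hispanic") * hispanic +
    sh_of("sgm") * sgm + sh_of("sex_female") * (sex == "female")
  latent <- shift + rnorm(n)

  ## --- exposure panel ------------------------------------------------------
  counts <- exposure_type_counts(cfg)
  meta <- build_exposure_meta(cfg, counts)
  p <- nrow(meta)
  lambda <- runif(p, cfg$latent_loading_range[1], cfg$latent_loading_range[2])
  Z <- matrix(rnorm(n * p), n, p)
  Z <- latent %o% lambda + sweep(Z, 2L, sqrt(1 - lambda^2), "*")

  # plant near-duplicates: partner = (base + s*noise)/sqrt(1+s^2), cor = r
  if (cfg$n_collinear_pairs > 0L) {
    s <- sqrt(1 / cfg$collinear_r^2 - 1)
    for (k in seq_len(cfg$n_collinear_pairs)) {
      b <- which(meta$collinear_role == "base")[k]
      d <- which(meta$collinear_role == "partner")[k]
      Z[, d] <- (Z[, b] + s * rnorm(n)) / sqrt(1 + s^2)
    }
  }

  X <- matrix(NA_real_, n, p, dimnames = list(NULL, meta$name))
  for (j in seq_len(p)) {
    X[, j] <- switch(meta$measurement[j],
      # threshold calibrated against the marginal score distribution, so
      # endorsement honours the configured probability despite subgroup
      # shifts in the latent burden
      binary = {
        mu <- lambda[j] * shift
        t_j <- uniroot(function(t)
          mean(pnorm(t - mu, lower.tail = FALSE)) - meta$endorsement[j],
          c(-12, 12), tol = 1e-10)$root
        as.numeric(Z[, j] > t_j)
      },
      ordinal = as.numeric(findInterval(Z[, j], ORDINAL_CUTS)),
      continuous = 10 + 5 * Z[, j])
  }

  ## --- true effects --------------------------------------------------------
  eligible <- meta$name[!meta$rare & meta$collinear_role == "none"]
  n_true <- cfg$n_true_risk + cfg$n_true_protective
  true_names <- sample(eligible, n_true)
  signs <- c(rep(1, cfg$n_true_risk), rep(-1, cfg$n_true_protective))
  mags <- runif(n_true, cfg$effect_size_range[1], cfg$effect_size_range[2])
  beta_std <- setNames(signs * mags, true_names)
  sd0 <- setNames(meta$sd0, meta$name)
  beta_raw <- setNames(numeric(p), meta$name)
  beta_raw[true_names] <- beta_std / sd0[true_names]
  null_set <- setdiff(meta$name, true_names)

  ## --- continuous outcome --------------------------------------------------
  cb <- cfg$covariate_beta
  cov_effect <- cb[["age"]] * age +
    cb[["sex_male"]] * (sex == "male") +
    cb[["race_black"]] * race_black +
    cb[["race_white"]] * race_white +
    cb[["hispanic"]] * hispanic +
    cb[["income_ordinal"]] * income_ordinal +
    cb[["parent_education"]] * parent_education +
    cb[["adversity"]] * adversity +
    cb[["nonsocial_screentime"]] *
      as.numeric(scale(nonsocial_screentime))
  burden <- as.numeric(X %*% beta_raw)
  u_site <- rnorm(cfg$n_sites, 0, sqrt(cfg$var_site))
  u_fam <- rnorm(cfg$n_families, 0, sqrt(cfg$var_family))
  outcome_continuous <- cfg$outcome_mean + cov_effect + burden +
    u_site[site_of_child] + u_fam[fam_of_child] +
    rnorm(n, 0, sqrt(cfg$var_resid))

  ## --- rare binary outcome (burden-driven logistic) ------------------------
  z_burden <- if (sd(burden) > 0) as.numeric(scale(burden)) else numeric(n)
  lp_slope <- cfg$binary_outcome_beta * z_burden
  alpha <- calibrate_logistic_intercept(lp_slope,
                                        cfg$binary_outcome_prevalence)
  outcome_binary <- rbinom(n, 1L, plogis(alpha + lp_slope))

  ## --- exposure missingness ------------------------------------------------
  X_obs <- X
  if (cfg$missing_rate > 0) {
    row_p <- missingness_row_prob(cfg, income_ordinal, age)
    mask <- matrix(runif(n * p) < row_p, n, p)
    X_obs[mask] <- NA_real_
  }

  cohort <- data.frame(participant_id, family_id, site_id,
                       subsample = NA_character_,
                       age, sex, race_black, race_white, hispanic, sgm,
                       income_ordinal, parent_education, adversity,
                       nonsocial_screentime,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(X_obs))
  cohort$outcome_continuous <- outcome_continuous
  cohort$outcome_binary <- outcome_binary

  cohort <- split_train_test(cohort, ratio = 0.5, seed = cfg$seed + 1L)

  truth <- structure(list(
    true_beta = beta_raw[true_names],
    beta_std = beta_std,
    null_set = null_set,
    rare_set = meta$name[meta$rare],
    collinear_pairs = collinear_pair_list(meta),
    variance_components = c(var_family = cfg$var_family,
                            var_site = cfg$var_site,
                            var_resid = cfg$var_resid),
    subgroup_shifts = cfg$subgroup_exposure_shift,
    latent_burden = setNames(burden, participant_id),
    binary_intercept = alpha,
    covariate_beta = cfg$covariate_beta,
    exposure_meta = meta,
    seed = cfg$seed), class = "sim_truth")

  list(cohort = cohort, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

# Exposure metadata table: names, measurement type, domain, endorsement,
# population SD under a standard-normal latent score, rare / collinear roles.
build_exposure_meta <- function(cfg, counts) {
  measurement <- rep(c("binary", "ordinal", "continuous"), counts)
  p <- length(measurement)
  domain <- character(p)
  name <- character(p)
  ib <- which(measurement == "binary")
  io <- which(measurement == "ordinal")
  ic <- which(measurement == "continuous")
  domain[ib] <- rep_len(c("apps", "parental_monitoring"), length(ib))
  domain[io] <- rep_len(c("overuse", "peer_interaction"), length(io))
  domain[ic] <- "screentime"
  name[ib] <- sprintf("%s_%02d",
                      ifelse(domain[ib] == "apps", "app", "pmon"), seq_along(ib))
  name[io] <- sprintf("%s_%02d",
                      ifelse(domain[io] == "overuse", "use", "peer"),
                      seq_along(io))
  name[ic] <- sprintf("st_hours_%02d", seq_along(ic))

  rare <- logical(p)
  if (cfg$n_rare > 0L) rare[ib[seq_len(cfg$n_rare)]] <- TRUE
  endorsement <- rep(NA_real_, p)
  endorsement[ib] <- runif(length(ib), cfg$endorsement_range[1],
                           cfg$endorsement_range[2])
  endorsement[rare] <- cfg$rare_endorsement

  collinear_role <- rep("none", p)
  if (cfg$n_collinear_pairs > 0L) {
    collinear_role[ic[seq_len(cfg$n_collinear_pairs)]] <- "base"
    collinear_role[ic[cfg$n_collinear_pairs +
                        seq_len(cfg$n_collinear_pairs)]] <- "partner"
  }

  sd0 <- rep(NA_real_, p)
  sd0[ib] <- sqrt(endorsement[ib] * (1 - endorsement[ib]))
  sd0[io] <- ordinal_sd0()
  sd0[ic] <- 5

  data.frame(name, measurement, domain, endorsement, sd0, rare,
             collinear_role, stringsAsFactors = FALSE)
}

collinear_pair_list <- function(meta) {
  bases <- meta$name[meta$collinear_role == "base"]
  partners <- meta$name[meta$collinear_role == "partner"]
  Map(c, bases, partners)
}

# Find the logistic intercept giving the target mean outcome probability.
calibrate_logistic_intercept <- function(lp_slope, prevalence,
                                         lower = -30, upper = 10) {
  f <- function(a) mean(plogis(a + lp_slope)) - prevalence
  if (f(lower) > 0 || f(upper) < 0)
    stop("infeasible config: binary_outcome_prevalence ", prevalence,
         " unreachable for the configured effect sizes", call. = FALSE)
  uniroot(f, c(lower, upper), tol = 1e-10)$root
}

# Per-row exposure missingness probability; MAR depends on income and age
# only (a mechanism the imputer's predictors can exploit).
missingness_row_prob <- function(cfg, income_ordinal, age) {
  if (cfg$missing_mechanism == "MCAR")
    return(rep(cfg$missing_rate, length(age)))
  lp <- -0.8 * as.numeric(scale(income_ordinal)) +
    0.4 * as.numeric(scale(age))
  f <- function(th) mean(plogis(th + lp)) - cfg$missing_rate
  th <- uniroot(f, c(-30, 10), tol = 1e-10)$root
  plogis(th + lp)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  cat(sprintf("  %d true effects (%d risk, %d protective), %d null exposures\n",
              length(x$true_beta), sum(x$true_beta > 0), sum(x$true_beta < 0),
              length(x$null_set)))
  cat(sprintf("  %d rare, %d collinear pairs; components (%.2f, %.2f, %.2f)\n",
              length(x$rare_set), length(x$collinear_pairs),
              x$variance_components[1], x$variance_components[2],
              x$variance_components[3]))
  invisible(x)
}

#' Exposure specifications from simulation ground truth
#'
#' Builds the per-variable metadata table used by the preparation pipeline
#' from a simulated cohort's `truth` object. Continuous exposures are flagged
#' for the upper-tail outlier rule.
#'
#' @param truth A `sim_truth` object from [simulate_cohort()].
#' @return A `data.frame` of class `exposure_spec` with columns
#'   `name`, `measurement`, `domain`, `combine_with`, `outlier_rule_applies`.
#' @export
exposure_specs <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  m <- truth$exposure_meta
  make_exposure_specs(name = m$name, measurement = m$measurement,
                      domain = m$domain)
}

#' Construct an exposure specification table
#'
#' @param name Unique variable names present in the cohort table.
#' @param measurement One of `"binary"`, `"ordinal"`, `"continuous"` per
#'   variable.
#' @param domain Conceptual domain label per variable.
#' @param combine_with Optional name of a sibling variable whose minutes are
#'   folded into this hours variable by [combine_hour_minute()]; `NA` for
#'   stand-alone variables.
#' @param outlier_rule_applies Logical; defaults to `TRUE` for continuous
#'   variables.
#' @return A validated `exposure_spec` data frame.
#' @export
make_exposure_specs <- function(name, measurement,
                                domain = "other",
                                combine_with = NA_character_,
                                outlier_rule_applies = measurement == "continuous") {
  measurement <- match.arg(measurement,
                           c("binary", "ordinal", "continuous"),
                           several.ok = TRUE)
  spec <- data.frame(name = name,
                     measurement = rep_len(measurement, length(name)),
                     domain = rep_len(domain, length(name)),
                     combine_with = rep_len(combine_with, length(name)),
                     outlier_rule_applies = rep_len(outlier_rule_applies,
                                                    length(name)),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(spec$name)) stop("exposure names must be unique")
  bad <- !is.na(spec$combine_with) & !(spec$combine_with %in% spec$name)
  if (any(bad))
    stop("combine_with references unknown variable(s): ",
         paste(spec$combine_with[bad], collapse = ", "))
  class(spec) <- c("exposure_spec", "data.frame")
  spec
}
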