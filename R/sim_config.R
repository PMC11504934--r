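#' Simulation configuration for a synthetic digital-exposome cohort
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cohort()]. Defaults describe the cohort the pipeline is designed
#' for: roughly 10,000 children in families nested within 21 study sites, 52
#' mixed-type digital exposures of which 7 are rare (<1% endorsement) and 4
#' pairs are nearly collinear (|r| > 0.9), a continuous outcome on the
#' T-score scale (mean 50) with family/site/residual variance components of
#' 5.75/0.11/20.16, a rare binary outcome (~1.5% prevalence) driven by the
#' same exposure burden, missing-at-random exposure data, and higher exposure
#' burden among Black, Hispanic and sexual/gender-minority (SGM) youth.
#'
#' @param n_sites Number of study sites.
#' @param n_families Number of families, allocated uniformly across sites.
#' @param mean_children_per_family Expected children per family (>= 1);
#'   family sizes are `1 + Poisson(mean - 1)`.
#' @param n_exposures Total number of exposure variables generated.
#' @param n_true_risk,n_true_protective Counts of exposures with positive /
#'   negative true effects on the continuous outcome.
#' @param exposure_type_mix Length-3 proportions (binary, ordinal,
#'   continuous) summing to 1.
#' @param endorsement_range Interval in (0,1) from which endorsement
#'   probabilities of non-rare binary exposures are drawn.
#' @param n_rare Number of binary exposures forced to `rare_endorsement`.
#' @param rare_endorsement Endorsement probability of rare binaries (< 0.01).
#' @param n_collinear_pairs Number of planted near-duplicate continuous
#'   exposure pairs.
#' @param latent_loading_range Interval in \[0, 1) from which each exposure's
#'   loading on the shared latent burden factor is drawn; `c(0, 0)` gives
#'   mutually independent exposures.
#' @param collinear_r Target population correlation of planted pairs
#'   (must exceed 0.9 so that pruning is exercised).
#' @param effect_size_range Interval of true standardized effect sizes
#'   (outcome points per SD of exposure).
#' @param var_family,var_site,var_resid Variance components of the continuous
#'   outcome: family-within-site, site, and residual.
#' @param outcome_mean,outcome_sd Nominal scale of the continuous outcome
#'   (T-score convention 50/10); `outcome_mean` is the model intercept.
#' @param binary_outcome_prevalence Target marginal prevalence of the binary
#'   outcome (e.g., lifetime suicide-attempt analog).
#' @param binary_outcome_beta Log-odds of the binary outcome per SD of the
#'   true exposure burden.
#' @param missing_rate Expected proportion of missing exposure cells.
#' @param missing_mechanism `"MCAR"` or `"MAR"` (logistic in household
#'   income and age).
#' @param subgroup_exposure_shift Named numeric vector of standardized shifts
#'   in latent exposure burden; recognized names are `race_black`,
#'   `hispanic`, `sgm`, `sex_female`.
#' @param covariate_beta Named numeric vector of fixed covariate effects on
#'   the continuous outcome (per raw covariate unit, except
#'   `nonsocial_screentime` which acts per SD).
#' @param seed Integer seed; identical configs give byte-identical cohorts.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_families = 200, n_exposures = 12, n_true_risk = 4,
#'                   n_rare = 1, n_collinear_pairs = 1, seed = 7)
#' str(cfg[c("n_exposures", "n_true_risk")])
sim_config <- function(n_sites = 21,
                       n_families = 8450,
                       mean_children_per_family = 1.2,
                       n_exposures = 52,
                       n_true_risk = 34,
                       n_true_protective = 1,
                       exposure_type_mix = c(binary = 0.5, ordinal = 0.3,
                                             continuous = 0.2),
                       endorsement_range = c(0.05, 0.60),
                       n_rare = 7,
                       rare_endorsement = 0.005,
                       n_collinear_pairs = 4,
                       collinear_r = 0.95,
                       latent_loading_range = c(0.4, 0.7),
                       effect_size_range = c(0.3, 1.0),
                       var_family = 5.75,
                       var_site = 0.11,
                       var_resid = 20.16,
                       outcome_mean = 50,
                       outcome_sd = 10,
                       binary_outcome_prevalence = 0.015,
                       binary_outcome_beta = log(1.76),
                       missing_rate = 0.10,
                       missing_mechanism = c("MAR", "MCAR"),
                       subgroup_exposure_shift = c(race_black = 0.8,
                                                   hispanic = 0.45,
                                                   sgm = 0.7),
                       covariate_beta = c(age = 0, sex_male = 0.3,
                                          race_black = -1.5, race_white = 0.4,
                                          hispanic = 0.2, income_ordinal = 0.15,
                                          parent_education = 0.13,
                                          adversity = 1.1,
                                          nonsocial_screentime = 0.33),
                       seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  cfg <- list(
    n_sites = as.integer(n_sites), n_families = as.integer(n_families),
    mean_children_per_family = mean_children_per_family,
    n_exposures = as.integer(n_exposures),
    n_true_risk = as.integer(n_true_risk),
    n_true_protective = as.integer(n_true_protective),
    exposure_type_mix = exposure_type_mix,
    endorsement_range = endorsement_range,
    n_rare = as.integer(n_rare), rare_endorsement = rare_endorsement,
    n_collinear_pairs = as.integer(n_collinear_pairs),
    collinear_r = collinear_r,
    latent_loading_range = latent_loading_range,
    effect_size_range = effect_size_range,
    var_family = var_family, var_site = var_site, var_resid = var_resid,
    outcome_mean = outcome_mean, outcome_sd = outcome_sd,
    binary_outcome_prevalence = binary_outcome_prevalence,
    binary_outcome_beta = binary_outcome_beta,
    missing_rate = missing_rate, missing_mechanism = missing_mechanism,
    subgroup_exposure_shift = subgroup_exposure_shift,
    covariate_beta = covariate_beta,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fail <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  if (cfg$n_sites < 1L) fail("n_sites must be positive")
  if (cfg$n_families < 1L) fail("n_families must be positive")
  if (cfg$mean_children_per_family < 1) fail("mean_children_per_family < 1")
  if (cfg$n_exposures < 1L) fail("n_exposures must be positive")
  if (cfg$n_true_risk < 0L || cfg$n_true_protective < 0L)
    fail("true effect counts must be non-negative")
  if (length(cfg$exposure_type_mix) != 3L)
    fail("exposure_type_mix must have 3 entries (binary, ordinal, continuous)")
  if (abs(sum(cfg$exposure_type_mix) - 1) > 1e-9)
    fail("exposure_type_mix must sum to 1")
  if (any(cfg$exposure_type_mix < 0)) fail("exposure_type_mix has negatives")
  if (cfg$n_true_risk + cfg$n_true_protective > cfg$n_exposures)
    fail("n_true_risk + n_true_protective exceeds n_exposures")
  if (length(cfg$endorsement_range) != 2L ||
      cfg$endorsement_range[1] <= 0 || cfg$endorsement_range[2] >= 1 ||
      diff(cfg$endorsement_range) < 0)
    fail("endorsement_range must be an interval inside (0,1)")
  if (cfg$n_rare > 0L && !(cfg$rare_endorsement > 0 &&
                           cfg$rare_endorsement < 0.01))
    fail("rare_endorsement must lie in (0, 0.01)")
  if (cfg$n_collinear_pairs > 0L &&
      !(cfg$collinear_r > 0.9 && cfg$collinear_r < 1))
    fail("collinear_r must lie in (0.9, 1)")
  if (length(cfg$effect_size_range) != 2L || diff(cfg$effect_size_range) < 0)
    fail("effect_size_range must be an interval")
  if (length(cfg$latent_loading_range) != 2L ||
      cfg$latent_loading_range[1] < 0 || cfg$latent_loading_range[2] >= 1 ||
      diff(cfg$latent_loading_range) < 0)
    fail("latent_loading_range must be an interval inside [0, 1)")
  if (cfg$var_family < 0 || cfg$var_site < 0) fail("variances must be >= 0")
  if (cfg$var_resid <= 0) fail("var_resid must be > 0")
  if (cfg$binary_outcome_prevalence <= 0 || cfg$binary_outcome_prevalence >= 1)
    fail("binary_outcome_prevalence must lie in (0,1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    fail("missing_rate must lie in [0,1)")
  counts <- exposure_type_counts(cfg)
  if (cfg$n_rare > counts["binary"])
    fail("n_rare exceeds the number of binary exposures implied by the mix")
  if (2L * cfg$n_collinear_pairs > counts["continuous"])
    fail("n_collinear_pairs needs 2 continuous exposures per pair")
  n_ineligible <- cfg$n_rare + 2L * cfg$n_collinear_pairs
  if (cfg$n_true_risk + cfg$n_true_protective >
      cfg$n_exposures - n_ineligible)
    fail(paste0("not enough non-rare, non-collinear exposures to carry ",
                cfg$n_true_risk + cfg$n_true_protective, " true effects"))
  cfg
}

# Deterministic integer split of n_exposures into (binary, ordinal,
# continuous) honouring the mix proportions (largest-remainder rounding).
exposure_type_counts <- function(cfg) {
  raw <- cfg$exposure_type_mix * cfg$n_exposures
  base <- floor(raw)
  rem <- cfg$n_exposures - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), c("binary", "ordinal", "continuous"))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d sites, %d families, ~%.2f children/family\n",
              x$n_sites, x$n_families, x$mean_children_per_family))
  cat(sprintf("  %d exposures (%d rare, %d collinear pairs), %d risk + %d protective effects\n",
              x$n_exposures, x$n_rare, x$n_collinear_pairs,
              x$n_true_risk, x$n_true_protective))
  cat(sprintf("  variance components: family %.2f, site %.2f, residual %.2f\n",
              x$var_family, x$var_site, x$var_resid))
  cat(sprintf("  missing %s at rate %.2f; seed %d\n",
              x$missing_mechanism, x$missing_rate, x$seed))
  invisible(x)
}

#' Read / write a simulation configuration as JSON
#'
#' @param path File path.
#' @return `read_sim_config()` returns a validated [sim_config()];
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("exposure_type_mix", "endorsement_range", "collinear_r",
              "latent_loading_range", "effect_size_range",
              "subgroup_exposure_shift", "covariate_beta"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param cfg A `sim_config` object.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- unclass(cfg)
  # keep names of named vectors (atomic vectors serialize as bare arrays)
  for (f in c("exposure_type_mix", "subgroup_exposure_shift",
              "covariate_beta"))
    out[[f]] <- as.list(out[[f]])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
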