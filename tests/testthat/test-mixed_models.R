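test_that("with zero cluster variance the fixed effects equal OLS", {
  zero_cov <- setNames(rep(0, 9), names(sim_config()$covariate_beta))
  zero_cov[c("adversity", "sex_male")] <- c(1.2, 0.5)
  # seed chosen so both variance components land on their boundary (the
  # probability of that event is substantial but not 1 under a true zero)
  cfg <- clean_cfg(n_families = 1500, var_family = 0, var_site = 0,
                   covariate_beta = zero_cov, seed = 70L)
  co <- simulate_cohort(cfg)$cohort
  terms <- c("adversity", "age", "sex")
  fit <- suppressWarnings(fit_lmm(co, "outcome_continuous", terms))
  ols <- lm(outcome_continuous ~ adversity + age + sex, data = co)
  expect_lt(max(abs(fit$beta$estimate - unname(coef(ols)))), 1e-4)
})

test_that("REML estimates beat every point of a brute-force grid", {
  d <- oracle_toy_clustered(seed = 99, n_sites = 2, fams_per_site = 3,
                            kids_per_fam = 2)
  fit <- suppressWarnings(fit_lmm(d, "y", character(0), quiet = TRUE))
  X <- matrix(1, nrow(d), 1)
  Zf <- oracle_indicator(d$family_id)
  Zs <- oracle_indicator(d$site_id)
  ll_fit <- oracle_reml_loglik(d$y, X, list(Zf, Zs),
                               list(fit$var_family_in_site, fit$var_site),
                               fit$var_resid)
  grid <- expand.grid(vf = seq(0, 8, length.out = 9),
                      vs = seq(0, 4, length.out = 7),
                      vr = seq(0.5, 6, length.out = 9))
  ll_grid <- mapply(function(vf, vs, vr)
    oracle_reml_loglik(d$y, X, list(Zf, Zs), list(vf, vs), vr),
    grid$vf, grid$vs, grid$vr)
  expect_gte(ll_fit, max(ll_grid) - 1e-6)
})

test_that("a single planted effect of 1.5 is recovered without bias", {
  # one true exposure, so no correlated-exposure confounding enters the
  # single-exposure model; standardized effect fixed at 1.5
  ests <- vapply(1:100, function(s) {
    cfg <- clean_cfg(n_families = 1500, n_true_risk = 1,
                     n_true_protective = 0,
                     effect_size_range = c(1.5, 1.5), seed = 7000 + s)
    sim <- simulate_cohort(cfg)
    v <- names(sim$truth$true_beta)[1]
    fit <- suppressWarnings(
      fit_lmm(sim$cohort, "outcome_continuous",
              c(v, dexwas:::EXWAS_COVARIATES), quiet = TRUE))
    fit$beta$estimate[fit$beta$term == v] / sim$truth$true_beta[[1]]
  }, numeric(1))
  # mean standardized estimate within 0.05 of 1.5
  expect_lt(1.5 * abs(mean(ests) - 1), 0.05)
})

test_that("marginal R2 follows its defining identity", {
  fake <- structure(list(var_family_in_site = 1, var_site = 1, var_resid = 4,
                         fixed_var = 2), class = "lmm_fit")
  expect_equal(marginal_r2(fake), 0.25)
  expect_equal(marginal_r2(fake, fixed_predictor_variance = 0), 0)
  fake0 <- structure(list(var_family_in_site = 0, var_site = 0, var_resid = 0,
                          fixed_var = 0), class = "lmm_fit")
  expect_error(marginal_r2(fake0), "zero")
})

test_that("recovered marginal R2 matches the analytic value at n ~ 10,000", {
  zero_cov <- setNames(rep(0, 9), names(sim_config()$covariate_beta))
  cfg <- clean_cfg(n_families = 8400, n_exposures = 6, n_true_risk = 3,
                   n_true_protective = 0, covariate_beta = zero_cov,
                   seed = 83L)
  sim <- simulate_cohort(cfg)
  burden <- sim$truth$latent_burden[sim$cohort$participant_id]
  analytic <- var(burden) / (var(burden) + 5.75 + 0.11 + 20.16)
  fit <- suppressWarnings(
    fit_lmm(sim$cohort, "outcome_continuous", names(sim$truth$true_beta),
            quiet = TRUE))
  expect_lt(abs(fit$marginal_r2 - analytic), 0.02)
})

test_that("the ICC identity is recomputable from any fit", {
  fx <- pipeline_fixture()
  fit <- fx$exwas
  f <- suppressWarnings(fit_lmm(fx$prep$cohort, "outcome_continuous",
                                c("age", "adversity"), quiet = TRUE))
  expect_equal(f$icc, icc(f$var_family_in_site, f$var_site, f$var_resid))
  expect_equal(f$icc, icc(f))
  expect_true(f$icc >= 0 && f$icc <= 1)
  expect_true(all(f$beta$ci_low <= f$beta$estimate &
                    f$beta$estimate <= f$beta$ci_high))
})

test_that("marginal R2 is monotone over nested fixed-effect sets", {
  fx <- pipeline_fixture()
  co <- fx$prep$cohort
  sets <- list(c("age"), c("age", "sex"), c("age", "sex", "adversity"),
               c("age", "sex", "adversity", "nonsocial_screentime"))
  r2 <- vapply(sets, function(tt)
    suppressWarnings(fit_lmm(co, "outcome_continuous", tt, quiet = TRUE))$marginal_r2,
    numeric(1))
  expect_true(all(diff(r2) >= -1e-9))
})

test_that("Wald intervals cover a true fixed effect about 95% of the time", {
  hits <- vapply(1:500, function(s) {
    set.seed(40000 + s)
    n_sites <- 12; fams_per_site <- 6; kids <- 3
    n <- n_sites * fams_per_site * kids
    site <- rep(seq_len(n_sites), each = fams_per_site * kids)
    fam <- rep(seq_len(n_sites * fams_per_site), each = kids)
    x <- rnorm(n)
    y <- 2 + 1.5 * x + rnorm(n_sites, 0, 1)[site] +
      rnorm(max(fam), 0, 1.5)[fam] + rnorm(n, 0, 2)
    d <- data.frame(participant_id = as.character(seq_len(n)),
                    family_id = sprintf("F%03d", fam),
                    site_id = sprintf("S%02d", site), x = x, y = y)
    f <- suppressWarnings(fit_lmm(d, "y", "x", quiet = TRUE))
    b <- f$beta[f$beta$term == "x", ]
    b$ci_low <= 1.5 && 1.5 <= b$ci_high
  }, logical(1))
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.98)
})

test_that("logistic odds ratios reproduce the 2x2 cross-product", {
  counts <- c(a = 10, b = 90, c = 5, d = 95)
  d <- data.frame(participant_id = as.character(1:200),
                  y = rep(c(1, 0, 1, 0), counts),
                  x = rep(c(1, 1, 0, 0), counts))
  f <- fit_logistic(d, "y", "x")
  expect_lt(abs(f$or$odds_ratio[f$or$term == "x"] -
                  oracle_or_2x2(10, 90, 5, 95)), 1e-3)

  # balanced table: MLE exactly zero, OR exactly 1
  d0 <- data.frame(participant_id = as.character(1:200),
                   y = rep(c(1, 0, 1, 0), c(10, 90, 10, 90)),
                   x = rep(c(1, 1, 0, 0), c(10, 90, 10, 90)))
  f0 <- fit_logistic(d0, "y", "x")
  expect_equal(f0$or$odds_ratio[f0$or$term == "x"], 1, tolerance = 1e-8)
})

test_that("logistic recovery: mean log-OR approaches the truth", {
  b <- vapply(1:50, function(s) {
    set.seed(50000 + s)
    n <- 1500
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-2 + 0.5 * x))
    d <- data.frame(participant_id = as.character(1:n), y = y, x = x)
    f <- fit_logistic(d, "y", "x")
    f$coef$estimate[f$coef$term == "x"]
  }, numeric(1))
  expect_lt(abs(mean(b) - 0.5), 0.05)
})

test_that("complete separation fails with the separating term named", {
  d <- data.frame(participant_id = as.character(1:40),
                  y = rep(c(0, 1), each = 20),
                  sep = rep(c(0, 1), each = 20),
                  x = rnorm(40))
  expect_error(fit_logistic(d, "y", c("sep", "x")), "sep")
})

test_that("single-class outcomes and missing columns are rejected", {
  d <- data.frame(participant_id = as.character(1:10), y = 0, x = rnorm(10))
  expect_error(fit_logistic(d, "y", "x"), "single class")
  expect_error(fit_logistic(d, "y", "nope"), "nope")
  expect_error(fit_lmm(d, "y", "nope"), "nope")
})
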