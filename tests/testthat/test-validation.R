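test_that("nested models share rows and delta R2 adds up exactly", {
  fx <- pipeline_fixture()
  nv <- run_nested_validation(fx$prep$cohort, fx$scores)
  expect_true(nv$converged)
  expect_equal(length(unique(nv$table$n_used)), 1L)
  expect_equal(sum(nv$table$delta_r2), nv$table$marginal_r2[4],
               tolerance = 1e-9)
  expect_equal(nv$table$delta_r2[1], nv$table$marginal_r2[1])
  # the score genuinely adds explained variance here
  expect_gt(nv$table$delta_r2[4], 0)
})

test_that("permuting the score column erases its delta R2", {
  fx <- pipeline_fixture()
  sc <- fx$scores
  set.seed(123)
  perm <- sc
  perm$z_score <- sample(perm$z_score)
  perm$raw_score <- sample(perm$raw_score)
  nv <- run_nested_validation(fx$prep$cohort, perm)
  expect_lt(nv$table$delta_r2[4], 0.005)
})

test_that("an attenuated alternative outcome explains less variance", {
  fx <- pipeline_fixture()
  co <- fx$prep$cohort
  burden <- fx$sim$truth$latent_burden[co$participant_id]
  set.seed(9)
  # same clustering noise scale, half the burden signal
  co$outcome_alt <- 50 + 0.5 * burden +
    rnorm(nrow(co), 0, sd(co$outcome_continuous - burden))
  main <- run_nested_validation(co, fx$scores)
  alt <- run_nested_validation(co, fx$scores, outcome = "outcome_alt")
  expect_lt(alt$table$delta_r2[4], main$table$delta_r2[4])
  expect_gt(alt$table$delta_r2[4], 0)
})

test_that("attempt models run the nested logistic sequence on common rows", {
  fx <- pipeline_fixture()
  am <- run_attempt_models(fx$prep$cohort, fx$scores)
  expect_named(am, c("score_demo_screentime", "plus_adversity"))
  expect_equal(am[[1]]$n_used, am[[2]]$n_used)
  or1 <- am[[1]]$or[am[[1]]$or$term == "score_z", ]
  expect_true(or1$ci_low <= or1$odds_ratio & or1$odds_ratio <= or1$ci_high)
})

test_that("log-odds per reported unit halve when the score SD doubles", {
  fx <- pipeline_fixture()
  sc2 <- fx$scores
  sc2$z_score <- 2 * sc2$z_score
  a <- run_attempt_models(fx$prep$cohort, fx$scores)
  b <- run_attempt_models(fx$prep$cohort, sc2)
  la <- a[[2]]$coef$estimate[a[[2]]$coef$term == "score_z"]
  lb <- b[[2]]$coef$estimate[b[[2]]$coef$term == "score_z"]
  expect_equal(lb, la / 2, tolerance = 1e-8)
})

test_that("the score-attempt odds ratio recovers the generator log-odds", {
  # the binary outcome is a logistic in the standardized burden; regressing
  # on the standardized burden itself recovers binary_outcome_beta
  b <- vapply(1:40, function(s) {
    cfg <- clean_cfg(n_families = 2200, n_exposures = 8, n_true_risk = 4,
                     binary_outcome_prevalence = 0.05, seed = 30000 + s)
    sim <- simulate_cohort(cfg)
    d <- sim$cohort
    d$zb <- as.numeric(scale(sim$truth$latent_burden[d$participant_id]))
    f <- fit_logistic(d, "outcome_binary", "zb")
    f$coef$estimate[f$coef$term == "zb"]
  }, numeric(1))
  expect_lt(abs(mean(b) - log(1.76)), 0.05)
})

test_that("null score-attempt paths cover OR = 1 near nominal rate", {
  hits <- vapply(1:60, function(s) {
    set.seed(60000 + s)
    n <- 1500
    d <- data.frame(participant_id = as.character(1:n),
                    y = rbinom(n, 1, 0.05), z = rnorm(n))
    f <- fit_logistic(d, "y", "z")
    row <- f$or[f$or$term == "z", ]
    row$ci_low <= 1 && 1 <= row$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.88)
})

test_that("top-decile binarization follows the tie and cutoff rules", {
  x <- 1:100
  b <- binarize_top_decile(x)
  expect_equal(which(b == 1), 91:100)

  # heavy ties at the cutoff go to the reference class
  xt <- c(rep(5, 95), 6:10)
  bt <- binarize_top_decile(xt)
  expect_lte(attr(bt, "prevalence"), 0.10)

  set.seed(2)
  bn <- binarize_top_decile(rnorm(5000))
  expect_gte(attr(bn, "prevalence"), 0.095)
  expect_lte(attr(bn, "prevalence"), 0.105)

  expect_error(binarize_top_decile(rep(1, 50)), "constant")
  expect_error(binarize_top_decile(c(1, 2, 3)), "10")
  xm <- c(1:20, NA)
  bm <- binarize_top_decile(xm)
  expect_true(is.na(bm[21]))
})

test_that("E-values reproduce closed-form cases and stay monotone", {
  # point estimate 1.95 treated as risk ratio: 1.95 + sqrt(1.95*0.95)
  e <- evalue(1.95, ci_low = 1.73, ci_high = 2.20)
  expect_equal(e$evalue_point, 1.95 + sqrt(1.95 * 0.95), tolerance = 1e-12)
  expect_equal(round(e$evalue_point, 1), 3.3)
  expect_equal(e$ci_limit, 1.73)
  expect_equal(e$evalue_ci, 1.73 + sqrt(1.73 * 0.73), tolerance = 1e-12)
  expect_equal(round(e$evalue_ci, 1), 2.9)

  expect_equal(evalue(1)$evalue_point, 1)
  # protective estimates invert first
  expect_equal(evalue(0.5)$evalue_point, evalue(2)$evalue_point)
  # common (non-rare) outcomes use the square-root correction
  expect_equal(evalue(4, rare_outcome = FALSE)$evalue_point,
               evalue(2)$evalue_point)
  # CI crossing 1 collapses the CI E-value to 1
  expect_equal(evalue(1.3, ci_low = 0.9, ci_high = 1.9)$evalue_ci, 1)
  # monotone in RR above 1
  es <- vapply(seq(1, 4, by = 0.1), function(r) evalue(r)$evalue_point,
               numeric(1))
  expect_true(all(diff(es) > 0))
  expect_true(all(es >= 1))
  expect_error(evalue(-1), "positive")
  expect_error(evalue(2, ci_low = 0), "positive")
})

test_that("the top-decile E-value analysis runs end to end", {
  fx <- pipeline_fixture()
  ev <- run_evalue_analysis(fx$prep$cohort, fx$scores)
  expect_s3_class(ev, "evalue_result")
  expect_gte(ev$evalue_point, 1)
  expect_gte(ev$evalue_point, ev$evalue_ci)
  expect_lte(ev$prevalence, 0.105)  # within 1/n of the decile, no ties
  # a positive score-outcome association is planted, so E > 1
  expect_gt(ev$evalue_point, 1)
})
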