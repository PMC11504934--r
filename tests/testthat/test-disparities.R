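test_that("Kruskal-Wallis H matches hand computation and stats oracle", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(x, g)
  expect_equal(kw$statistic, 7.2)  # hand-ranked: 12/(9*10)*(6+0+6)*9 terms
  expect_equal(kw$df, 2L)

  # identical groups: no separation
  kw0 <- kruskal_wallis(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p, 1)

  # tie-corrected H equals the stats:: implementation on random data
  set.seed(12)
  for (i in 1:10) {
    xs <- sample(1:6, 60, TRUE)  # heavy ties
    gs <- sample(c("a", "b", "c", "d"), 60, TRUE)
    kt <- kruskal.test(xs, factor(gs))
    mine <- kruskal_wallis(xs, gs)
    expect_equal(mine$statistic, unname(kt$statistic), tolerance = 1e-12)
    expect_equal(mine$p, kt$p.value, tolerance = 1e-12)
  }
  expect_error(kruskal_wallis(1:4, rep(c("a", "b"), 2)), ">= 3")
})

test_that("configured subgroup shifts separate score distributions", {
  fx <- pipeline_fixture()
  d <- fx$prep$cohort[fx$prep$cohort$subsample == "test", ]
  r3 <- derive_race3(d)
  kw <- kruskal_wallis(fx$scores$z_score, r3)
  expect_lt(kw$p, 0.001)
  expect_gt(kw$medians[["nh_black"]], kw$medians[["nh_white"]])

  mw <- mann_whitney_rb(fx$scores$z_score,
                        ifelse(d$sgm == 1, "sgm", "non_sgm"))
  expect_lt(mw$p, 0.001)
})

test_that("Dunn pairwise z follows the pooled-rank formula with Holm", {
  set.seed(3)
  x <- c(rnorm(20), rnorm(25, 1), rnorm(30, 2))
  g <- rep(c("a", "b", "c"), c(20, 25, 30))
  dn <- dunn_holm(x, g)
  N <- length(x)
  r <- rank(x)
  # independent recomputation for the (a, b) pair
  se_ab <- sqrt((N * (N + 1) / 12) * (1 / 20 + 1 / 25))  # no ties here
  z_ab <- (mean(r[g == "a"]) - mean(r[g == "b"])) / se_ab
  expect_equal(dn$z[dn$group1 == "a" & dn$group2 == "b"], z_ab,
               tolerance = 1e-12)
  expect_equal(dn$p_adj, holm_adjust(dn$p))
  expect_true(all(dn$p_adj >= dn$p))

  # two identical groups among three: their z is exactly zero
  x2 <- c(1:5, 1:5, 6:10)
  g2 <- rep(c("a", "b", "c"), each = 5)
  dn2 <- dunn_holm(x2, g2)
  expect_equal(dn2$z[dn2$group1 == "a" & dn2$group2 == "b"], 0)

  # antisymmetry under group order swap
  gf <- factor(g, levels = c("c", "b", "a"))
  dn3 <- dunn_holm(x, gf)
  z_ba <- dn3$z[dn3$group1 == "b" & dn3$group2 == "a"]
  expect_equal(z_ba, -z_ab, tolerance = 1e-12)
})

test_that("Holm adjustment matches hand computation and p.adjust", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(21)
  for (i in 1:10) {
    p <- runif(sample(2:12, 1))
    expect_equal(holm_adjust(p), p.adjust(p, "holm"))
  }
  expect_error(holm_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("rank-biserial matches brute-force pair counting", {
  # complete separation
  expect_equal(mann_whitney_rb(c(4, 5, 6, 1, 2, 3),
                               rep(c("hi", "lo"), each = 3))$effect_size, 1)
  # tied copies of equal size
  expect_equal(mann_whitney_rb(c(1, 2, 3, 1, 2, 3),
                               rep(c("a", "b"), each = 3))$effect_size, 0)
  # first group entirely below: U1 = 0, r = -1
  mw <- mann_whitney_rb(c(1, 2, 3, 4), rep(c("a", "b"), each = 2))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$effect_size, -1)

  set.seed(31)
  for (i in 1:15) {
    n1 <- sample(3:40, 1); n2 <- sample(3:40, 1)
    x1 <- sample(1:10, n1, TRUE); x2 <- sample(1:10, n2, TRUE)
    mine <- mann_whitney_rb(c(x1, x2), rep(c("g1", "g2"), c(n1, n2)))
    expect_equal(mine$effect_size, oracle_rank_biserial(x1, x2),
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_rb(1:3, c("a", "a", "a")), "2 groups")
})

test_that("two-group rank tests agree: KW core equals MW normal approx", {
  set.seed(17)
  x <- rnorm(40)  # tie-free
  g <- rep(c("a", "b"), each = 20)
  mw <- mann_whitney_rb(x, g)
  # KW with k = 2 is the square of the MW z-statistic
  r <- rank(x)
  N <- 40
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  expect_equal(pchisq(H, 1, lower.tail = FALSE), mw$p, tolerance = 1e-6)
})

test_that("interaction terms recover a planted slope difference", {
  ests <- vapply(1:30, function(s) {
    cfg <- clean_cfg(n_families = 900, seed = 70000 + s)
    # outer draws must not replay the generator stream
    set.seed(170000 + s)
    sim <- simulate_cohort(cfg)
    d <- sim$cohort
    d$subsample <- NULL  # score the whole simulated table
    fake_z <- rnorm(nrow(d))
    slope <- ifelse(d$sgm == 1, 0.5, 1.0)   # group B slope minus A = -0.5
    d$outcome_continuous <- 50 + slope * fake_z + rnorm(nrow(d), 0, 2)
    scores <- data.frame(participant_id = d$participant_id,
                         raw_score = fake_z, z_score = fake_z)
    ir <- fit_interactions(d, scores, group = "sgm")
    ir$terms$estimate
  }, numeric(1))
  expect_lt(abs(mean(ests) - (-0.5)), 0.1)
})

test_that("null interactions cover zero and slopes pool correctly", {
  covered <- logical(40)
  for (s in 1:40) {
    cfg <- clean_cfg(n_families = 700, seed = 80000 + s)
    # outer draws must not replay the generator stream
    set.seed(180000 + s)
    sim <- simulate_cohort(cfg)
    d <- sim$cohort
    d$subsample <- NULL  # score the whole simulated table
    fake_z <- rnorm(nrow(d))
    d$outcome_continuous <- 50 + 1.0 * fake_z + rnorm(nrow(d), 0, 2)
    scores <- data.frame(participant_id = d$participant_id,
                         raw_score = fake_z, z_score = fake_z)
    ir <- fit_interactions(d, scores, group = "sex")
    b <- ir$terms
    covered[s] <- b$estimate - 1.96 * b$se <= 0 & 0 <= b$estimate + 1.96 * b$se
    if (s == 1) {
      # stratified slopes bracket the pooled slope under the null
      sl <- ir$stratified
      expect_true(all(!sl$low_n))
      pooled <- 1.0
      expect_true(all(abs(sl$estimate - pooled) < 0.2))
      expect_setequal(sl$group, c("female", "male"))
    }
  }
  expect_gte(mean(covered), 0.85)
})

test_that("small strata are flagged rather than fitted", {
  fx <- pipeline_fixture()
  d <- fx$prep$cohort
  d$tiny_group <- as.integer(seq_len(nrow(d)) <= 30)
  ir <- fit_interactions(d, fx$scores, group = "tiny_group")
  expect_true(ir$stratified$low_n[ir$stratified$group == "tiny_group_1"])
})

test_that("race3 derivation yields mutually exclusive labels", {
  fx <- pipeline_fixture()
  r3 <- derive_race3(fx$prep$cohort)
  d <- fx$prep$cohort
  expect_true(all(is.na(r3) | r3 %in% c("nh_white", "nh_black", "hispanic")))
  expect_true(all(r3[d$hispanic == 1] == "hispanic", na.rm = TRUE))
  expect_true(all(r3[d$race_black == 1 & d$hispanic == 0] == "nh_black"))
})
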