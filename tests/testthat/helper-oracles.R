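# Independent oracles kept deliberately naive: dense linear algebra, brute
# force pair counting, closed forms. They never call package internals.

# Restricted (REML) log-likelihood of y = X b + sum_k u_k + e with given
# variance components, fixed effects profiled out. Dense algebra, usable
# only at toy sizes.
oracle_reml_loglik <- function(y, X, Z_list, v_list, v_resid) {
  n <- length(y)
  V <- diag(v_resid, n)
  for (k in seq_along(Z_list))
    V <- V + v_list[[k]] * tcrossprod(Z_list[[k]])
  Vi <- solve(V)
  B <- t(X) %*% Vi %*% X
  beta <- solve(B, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
                       determinant(B, logarithm = TRUE)$modulus +
                       t(r) %*% Vi %*% r))
}

# Indicator matrix for a grouping vector.
oracle_indicator <- function(g) {
  g <- as.factor(g)
  Z <- matrix(0, length(g), nlevels(g))
  Z[cbind(seq_along(g), as.integer(g))] <- 1
  Z
}

# Cliff's delta / rank-biserial by brute-force pair enumeration.
oracle_rank_biserial <- function(x1, x2) {
  wins <- 0
  for (a in x1) wins <- wins + sum(a > x2) + 0.5 * sum(a == x2)
  2 * wins / (length(x1) * length(x2)) - 1
}

# 2x2 cross-product odds ratio from exposed/unexposed event counts.
oracle_or_2x2 <- function(a, b, c, d) (a * d) / (b * c)

# Benjamini-Hochberg step-up by direct definition (quadratic scan).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[o[i]] <- min(1, min(p[o[js]] * m / js))
  }
  q
}

# Build a small balanced clustered dataset for REML oracle tests.
oracle_toy_clustered <- function(seed = 99, n_sites = 2, fams_per_site = 3,
                                 kids_per_fam = 2, vf = 4, vs = 1, vr = 2) {
  set.seed(seed)
  site <- rep(seq_len(n_sites), each = fams_per_site * kids_per_fam)
  fam <- rep(seq_len(n_sites * fams_per_site), each = kids_per_fam)
  y <- 10 + rnorm(n_sites, 0, sqrt(vs))[site] +
    rnorm(n_sites * fams_per_site, 0, sqrt(vf))[fam] +
    rnorm(length(site), 0, sqrt(vr))
  data.frame(participant_id = sprintf("P%02d", seq_along(y)),
             family_id = sprintf("F%02d", fam),
             site_id = sprintf("S%02d", site),
             y = y, stringsAsFactors = FALSE)
}
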