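---
title: "Screening the digital exposome: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening the digital exposome: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Adolescents accumulate many digital exposures at once — hours of screentime,
specific apps, problematic patterns of use, adverse peer interactions such
as cyberbullying — and these exposures are correlated with one another and
unevenly distributed across subpopulations. Studying them one at a time
invites multiple-comparison and collinearity problems. The exposome-wide
association study (ExWAS) borrows the GWAS playbook instead: screen every
exposure against the outcome in a uniform model, control the false-discovery
rate across the whole screen, and condense the survivors into a single
weighted risk score that can be validated in held-out data.

`dexwas` implements that pipeline for cohorts with the two-level clustering
typical of multi-site child studies (children within families within study
sites), together with a synthetic-cohort generator that stands in for the
restricted cohort data such studies rely on.

## The models

**Screening.** For each exposure $x_j$ the training subsample is fitted
with the linear mixed model

$$y_{ifs} = \beta_0 + \beta_j x_{j,ifs} + \gamma^\top c_{ifs}
  + u_{f(s)} + v_s + \varepsilon_{ifs},$$

where $y$ is a continuous psychopathology score on the T-score scale,
$c$ holds the screening covariates (age, sex, Black and White race
indicators, Hispanic ethnicity), and $u_{f(s)} \sim N(0, \sigma^2_{f})$,
$v_s \sim N(0, \sigma^2_{s})$, $\varepsilon \sim N(0, \sigma^2_{e})$ are
the family-within-site, site and residual components, estimated by REML.
Two-sided p-values use the large-sample normal reference for
$t = \hat\beta/\mathrm{se}$; with thousands of independent families the
difference from finite-degree-of-freedom references is negligible, and 95%
intervals are Wald ($\pm 1.96\,\mathrm{se}$). Benjamini–Hochberg adjustment
runs over exactly the set of screened exposures; exposures with $q < 0.05$
are classified risk ($\hat\beta > 0$) or protective ($\hat\beta < 0$).

**Scoring.** For each held-out participant the raw exposomic risk score is
$\sum_{j \in \text{significant}} \hat\beta_j x_{ij}$ — coefficients kept on
their original per-unit scale, protective coefficients entering with their
sign — then z-scored within the scored subsample. Exposures are *not*
re-standardized before weighting; the final z-scoring restores
comparability while keeping the aggregation interpretable as predicted
outcome points.

**Validation.** Four nested mixed models on the testing subsample
(demographics with household income and parent education; + non-social
screentime; + non-digital adversity; + the score) are fitted on one common
row set — rows missing any largest-model variable are deleted up front, so
Nakagawa marginal $R^2$, $\mathrm{ICC} = (\sigma^2_f + \sigma^2_s)/
(\sigma^2_f + \sigma^2_s + \sigma^2_e)$, and the $\Delta R^2$ ladder are
comparable by construction ($\sum_m \Delta R^2_m = R^2_{M4}$ exactly). The
rare binary outcome (lifetime suicide-attempt analog) uses plain logistic
regression per one standard deviation of the score; site and family
clustering are not modelled there, a documented limitation.

**Sensitivity to unmeasured confounding.** The continuous outcome is
binarized at its empirical top decile (ties to the reference class), a
logistic model with all Model-4 covariates is fitted, and the score's odds
ratio is converted to an E-value, $E = RR + \sqrt{RR(RR-1)}$, treating the
odds ratio as a risk ratio because a 10%-prevalence outcome is rare enough
for that approximation; the square-root correction is available for common
outcomes. The confidence-limit E-value uses the limit closer to 1 and
collapses to 1 when the interval crosses 1.

**Disparities.** Differential *exposure* is tested nonparametrically:
Kruskal–Wallis (tie-corrected H) across the three mutually exclusive
race/ethnicity groups with Dunn–Holm pairwise follow-ups, and Mann–Whitney
tests with the rank-biserial coefficient $\hat r = 2U_1/(n_1 n_2) - 1$
(positive when the first-listed group tends larger; equivalent to Cliff's
delta) for two-group contrasts. Differential *effects* add score-by-group
products to the validation model and refit the model within strata for
simple slopes; strata under 50 children are flagged rather than fitted.

## What the generator emulates — and what it does not

`sim_config()` defaults describe the cohort this pipeline targets:
~10,000 children (8,450 families × ~1.2 children, 21 sites), 52 exposures
in a binary/ordinal/continuous mix of 50/30/20%, 7 rare binaries (0.5%
endorsement), 4 planted near-duplicate pairs (r = 0.95), outcome variance
components 5.75 / 0.11 / 20.16 (family / site / residual, ICC ≈ 0.23),
intercept 50 on the T-score scale, a ~1.5% binary outcome whose log-odds
rise by log(1.76) per SD of true exposure burden (intercept found by root
search so the configured prevalence is hit exactly in expectation), 10%
missing-at-random exposure data driven by income and age, and higher
latent exposure burden for Black (+0.8 SD), Hispanic (+0.45 SD) and
sexual/gender-minority (+0.7 SD) youth — shifts chosen to reproduce the
ordering and rough spacing of reported score medians. 35 signed effects
(34 risk, 1 protective) are drawn from 0.3–1.0 outcome points per SD of
exposure: large enough that a training half of ~5,000 detects all of them,
small enough that single exposures stay minor contributors.

All exposures load on one latent burden factor (loadings U(0.4, 0.7)),
which is what produces realistic inter-exposure correlation, the subgroup
differences, and the collinear structure that pruning must handle. Rare
binary thresholds are calibrated against the *marginal* latent distribution
(including subgroup shifts), so configured endorsements hold in the
population actually generated.

The generator does **not** mimic item wordings, branching logic, app-level
marginals, heavy-tailed follower counts (continuous exposures are
Gaussian), or informative missingness beyond the income/age mechanism. A
green test therefore establishes that the *procedures* behave as specified
on data with the right structure — not that any real cohort's estimates
would be reproduced.

### Why the recovery criteria use the independent-exposure world

Two checks run with the latent loadings set to zero
(`latent_loading_range = c(0, 0)`) and no survey missingness:
coefficient-recovery ("bias < 5% of effect size") and the mixed true/null
empirical-FDR bound. Under the correlated default, a *marginal* screen
estimates marginal associations: an exposure with no direct effect but
correlated with the burden carries a genuine nonzero marginal coefficient
(the real study saw 35 of 41 exposures significant for exactly this
reason). Deviation of marginal from partial coefficients is a property of
the design, not estimator bias, and "null" in an FDR statement must mean
*marginally* null. The independent world makes planted and estimated
quantities commensurable; every other test exercises the correlated
default.

## Numerical choices

- **Quartiles for the outlier fence** are type-1 (inverse ECDF), so on
  small samples the fence derives from observed values; the rule is
  one-sided (`> Q3 + k·IQR`, default k = 3, `Inf` disables) and removal
  sets cells to missing for the imputer to refill, keeping n constant.
- **Collinearity pruning** is the greedy mean-absolute-correlation
  heuristic: repeatedly take the worst pair above |r| = 0.9
  (pairwise-complete Pearson, training rows only) and drop the member with
  the larger mean |r| against all remaining exposures; ties resolve by
  name order (alphabetically later name drops). Zero-variance columns are
  excluded with a warning.
- **Imputation** follows the iterative random-forest scheme: mean/mode
  initialisation, visitation by increasing missingness, per-variable
  bagged regression forests (Rcpp; mtry = p/3 for continuous targets,
  √p for binary/ordinal, matching classic forest defaults), stopping at
  the first sweep where the normalized change increases for every variable
  type present and returning the preceding iterate. Binary predictions
  threshold at 0.5; ordinal predictions round and clamp to observed
  levels. Observed cells are never altered.
- **Variance components** are bounded at zero; singular fits warn (once,
  suppressible in screening loops) and report the component as 0.
- **The ExWAS loop** reuses one model structure per screen and swaps the
  exposure column, which halves per-fit cost; a dedicated test asserts
  records are bit-identical to independent refits, and any missingness in
  exposures (the list-wise sensitivity variant) falls back to per-exposure
  fitting with its own deletion.
- **Ties** in the top-decile binarization go to the reference class, so tie
  inflation can only lower the high-score prevalence.
- **Determinism**: every stochastic routine takes a seed, derives internal
  seeds arithmetically, and restores the caller's RNG state; identical
  configuration and seed give byte-identical cohorts, imputations and
  screens.

## Open design points, resolved

- The E-value analysis treats the top-decile odds ratio as a risk ratio
  (rare-outcome reading) rather than applying the square-root correction —
  the reading consistent with the reported 3.3 / 2.9 values.
- Non-social screentime and the risk score are z-scored in the merged
  testing sample *before* model-specific deletion, and odds ratios are
  reported per 1 SD of the score.
- Interaction models add one grouping at a time (sex, race/ethnicity
  indicators, SGM), mirroring a one-at-a-time analysis plan; the
  race/ethnicity grouping uses three mutually exclusive labels and leaves
  residual categories out of the three-group tests.
- Suicide-attempt models share the largest-model row set within their
  sequence.
- Exact small-sample Mann–Whitney p-values are not implemented; every
  intended use has group sizes far beyond the normal-approximation regime.

## Known limitations

The logistic stage ignores clustering; family variance is weakly
identified when nearly all families contribute one child (estimates are
unbiased but noisy — visible in the generator tests); scores inherit the
marginal-screening double-counting of correlated exposures (no shrinkage
or joint modelling, by design); and the generator's Gaussian continuous
exposures understate the heavy tails that motivate the outlier rule, so
that rule is exercised mainly by constructed fixtures.
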