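# dexwas

Exposome-wide association screening and risk scoring for **digital
exposures** — screentime, app use, problematic/addictive use patterns,
parental monitoring, adverse peer interactions — against youth mental
health outcomes in cohorts where children are nested in families nested in
study sites.

Who it is for: biostatisticians and epidemiologists who want the full
ExWAS workflow (curation → screen → FDR → weighted score → held-out
validation → sensitivity and disparity analyses) as reusable, tested
building blocks, plus a seeded synthetic-cohort generator with ground
truth for power studies and method checks, because the cohort data such
analyses target are typically access-restricted.

## The method in brief

1. **Split** the cohort into training/testing halves by whole families,
   stratified by site.
2. **Curate** exposures: merge split hour/minute items, drop binary items
   with < 1% endorsement, set extreme upper-tail values
   (> Q3 + 3·IQR) to missing, impute missing exposures per subsample with
   iterative random forests, and greedily prune collinear pairs
   (|r| > 0.9, decided on the training half only).
3. **Screen**: one linear mixed model per exposure on the training half,

   y = β₀ + βⱼ xⱼ + γᵀc + u_family(site) + v_site + ε,

   REML, demographic covariates c, normal-reference p-values,
   Benjamini–Hochberg q over the screened set; q < 0.05 ⇒ risk (βⱼ > 0)
   or protective (βⱼ < 0).
4. **Score** each testing-half participant: raw = Σ βⱼxⱼ over significant
   exposures (signed, original units), then z-scored.
5. **Validate**: nested mixed models M1 (demographics) → M2 (+ non-social
   screentime) → M3 (+ non-digital adversity) → M4 (+ score) on one common
   row set, with Nakagawa marginal R², ΔR² and ICC; logistic models for a
   rare suicide-attempt analog (OR per SD of score); E-value sensitivity
   analysis, E = RR + √(RR(RR−1)), on the top-decile binarized outcome.
6. **Disparities**: Kruskal–Wallis + Dunn–Holm across race/ethnicity,
   Mann–Whitney with rank-biserial r̂ for two-group contrasts
   (differential exposure), and score×group interactions with stratified
   simple slopes (differential effects).

## Worked example

```r
library(dexwas)

cfg   <- sim_config(n_families = 2400, n_exposures = 20, n_true_risk = 6,
                    n_true_protective = 1, n_rare = 2, n_collinear_pairs = 2,
                    seed = 424)
sim   <- simulate_cohort(cfg)
prep  <- run_prep(sim$cohort, exposure_specs(sim$truth), n_trees = 15, seed = 7)
prep$report
#> <prep_report>
#>   20 exposures in, 16 retained
#>   dropped for low endorsement (2): app_01, pmon_02
#>   dropped as collinear (2): st_hours_02, st_hours_01
#>   outlier cells removed: 0 (k = 3)
#>   imputation sweeps: train 4, test 3
```

The report mirrors the curation story: both planted rare binaries fall to
the endorsement filter, one member of each planted near-duplicate pair
falls to pruning, and imputation converged in a few sweeps.

```r
exwas  <- run_exwas(prep$cohort, prep$specs$name, specs = prep$specs)
head(exwas[order(exwas$p), c("exposure","beta","ci_low","ci_high","t","q")], 4)
#>  exposure  beta ci_low ci_high    t        q
#>    use_01 0.996  0.755    1.24 8.08 7.49e-15
#>   peer_06 0.967  0.731    1.20 8.03 7.49e-15
#>    app_03 2.206  1.633    2.78 7.55 2.35e-13
#>    app_07 2.765  2.002    3.53 7.10 4.98e-12
```

Coefficients are outcome points per exposure unit — e.g. endorsing
`app_07` is associated with a 2.8-point higher psychopathology T-score in
a separate covariate-adjusted mixed model. Because exposures share a
latent burden factor, correlated null exposures also screen significant
(here 16/16) — exactly the marginal-screening behaviour the weighted score
is built on.

```r
scores <- compute_scores(prep$cohort, exwas)
run_nested_validation(prep$cohort, scores)
#>  model marginal_r2 delta_r2 n_used
#>     M1     0.01506 0.015059   1457
#>     M2     0.01653 0.001471   1457
#>     M3     0.03630 0.019765   1457
#>     M4     0.10930 0.073009   1457
```

Demographics explain ~1.5% of outcome variance; adding the digital
exposomic score lifts the fixed-effects (marginal) R² to 10.9% — a ΔR² of
7.3 points over screentime and adversity, on identical rows.

```r
run_evalue_analysis(prep$cohort, scores)
#> <evalue_result> OR = 1.605 -> E = 2.59 (CI limit 1.344 -> E = 2.02)

kruskal_wallis(scores$z_score,
               derive_race3(subset(prep$cohort, subsample == "test")))
#> <group_test> kruskal_wallis over nh_white, nh_black, hispanic
#>   statistic = 103.1367 (df = 2), p = 4.02e-23
#>   medians: nh_white = -0.328, nh_black = 0.471, hispanic = 0.0977
```

An unmeasured confounder would need a 2.6-fold association with both the
score and high outcome scores to explain the association away; score
medians differ across race/ethnicity groups as configured in the
generator's subgroup shifts.

A command-line front end covering the same steps is installed as
`exec/dexwas` (subcommands `simulate`, `prep`, `screen`, `score`,
`validate`, `disparities`); see `?dexwas_cli`.

## Method documentation

`vignettes/digital-exposome-pipeline.Rmd` describes the models and their
assumptions, every tunable parameter with units and defaults, what the
synthetic cohort does and does not emulate (and hence what a green test
establishes), numerical conventions (quantile type, tie-breaks, stopping
rules, degenerate inputs), and known limitations.
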