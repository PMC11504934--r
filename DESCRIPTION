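Package: dexwas
Title: Digital Exposome-Wide Association Screening and Risk Scoring
Version: 1.0.0
Authors@R:
    person("Dexwas", "Developers", email = "dexwas@users.noreply.github.com",
           role = c("aut", "cre"))
Description: Tools for exposome-wide association studies (ExWAS) of digital
    and social-media exposures in clustered youth cohorts. Implements a
    seeded synthetic-cohort generator with family-within-site nesting and
    known ground truth, exposure curation (endorsement filtering, outlier
    handling, hour/minute merging, greedy collinearity pruning, iterative
    random-forest imputation), per-exposure linear mixed-model screening
    with Benjamini-Hochberg false-discovery-rate correction, construction
    of coefficient-weighted exposomic risk scores in a held-out subsample,
    nested mixed-model validation with Nakagawa marginal R-squared and
    intra-class correlation, logistic models for rare binary outcomes,
    E-value sensitivity analysis for unmeasured confounding, and
    nonparametric disparity tests (Kruskal-Wallis, Dunn-Holm, Mann-Whitney
    with rank-biserial effect sizes) with interaction and stratified-slope
    models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
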