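Package: opennest
Title: Nest Density, Survival, and Productivity from Replicated Nest Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates grassland-songbird nest density, daily nest survival,
    and plot-scale productivity from replicated nest-search surveys with
    imperfect detection. Implements the open-population (Dail-Madsen)
    N-mixture likelihood for replicated nest counts with recruitment and
    survival dynamics, empirical-Bayes prediction of latent nest abundance,
    a daily nest-survival exposure likelihood with covariates at nest-site
    and plot scales, QAICc model selection with parametric-bootstrap
    overdispersion estimation, vegetation-sampling support statistics, and
    a synthetic-study generator that reproduces the sampling design so
    every stage of the pipeline can be verified against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
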