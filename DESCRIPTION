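Package: climsent
Title: Spatio-Temporal Relative-Risk Modelling of Climate-Health Stressors
    and Negative Social-Media Sentiment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking weekly climate-health exposures (maximum
    temperature, pollen concentrations, drought index, heat-attributable
    mortality, West Nile virus incidence) to counts of negative-sentiment
    social-media posts aggregated over regions and weeks.  Implements
    exposure categorisation into ordered levels, an exact dynamic-programming
    solver for the one-dimensional sparse fused lasso used to detect
    country-level change points, and a hierarchical Poisson relative-risk
    model with an iid spatial effect, an AR(1) temporal field and
    categorical exposure random effects, fitted by penalised likelihood
    with Laplace-approximate posteriors and empirical-Bayes hyperparameters.
    Includes a seeded synthetic-panel generator with known ground truth for
    end-to-end validation, Pearson-residual diagnostics, an MCMC
    cross-check, and a pipeline driver producing exposure-response summaries
    (percent change in relative risk with 95% intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
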