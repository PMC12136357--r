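Package: planktrend
Title: Hierarchical Bayesian Trend Analysis of Diatom and Dinoflagellate
    Carbon Biomass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts taxon-resolved plankton abundance records to
    functional-group carbon biomass with allometric volume-to-carbon
    models, aggregates samples into province by latitude-band by month
    bins with half-minimum zero imputation, constructs sea-surface
    temperature anomalies from a Bayesian decomposition of gridded SST,
    and fits hierarchical Bayesian Time-Space-Temperature and Time-Space
    models (the latter with Extended Bayesian LASSO shrinkage on decadal
    step effects) to log biomass and the logit diatom index. Includes a
    synthetic-data generator emulating Continuous Plankton Recorder
    sampling, posterior predictive checks with Bayesian p-values,
    Bayesian R-squared and leave-one-predictor-out variable importance,
    and reporting of trends as percent change per year and compounded
    multi-decade change.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
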