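Package: romicast
Title: Probabilistic Mortality Forecasting with Rates of Mortality Improvement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forecasts age-specific mortality by modelling rates of mortality
    improvement (ROMIs) with Bayesian hierarchical core models (a linear and a
    log-linear "exponential" trend model), sampled by an adaptive
    Metropolis-within-Gibbs algorithm. Forecast ROMI draws can be blended with
    the mean trend of reference countries to model mortality convergence,
    propagated to quantile surfaces of future death rates, and summarised as
    life expectancy with prediction intervals. Includes HMD-style fixed-width
    and CSV readers for mortality surfaces, P-spline smoothing of death rates,
    period life-table construction, forecast validation by error and
    interval-coverage metrics, MCMC diagnostics including the Raftery-Lewis
    run-length diagnostic, and a synthetic-data generator for fully
    self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    splines,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    coda,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'surfaces.R'
    'hmd_io.R'
    'smoothing.R'
    'romi.R'
    'priors.R'
    'core_models.R'
    'mcmc.R'
    'diagnostics.R'
    'lifetable.R'
    'forecast.R'
    'validation.R'
    'synthetic.R'
    'pipeline.R'
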