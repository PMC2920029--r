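Package: mesoproj
Title: Bayesian Projection of Mesothelioma Mortality from Reconstructed
    Asbestos Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a Poisson regression model of male mesothelioma mortality
    in which the expected death count at each age and calendar year is a
    lagged, power-of-time weighted sum of past population asbestos exposure,
    modified by an age-specific exposure potential, fibre clearance, a
    background rate not attributable to asbestos, and an optional diagnostic
    completeness trend.  The population exposure history is reconstructed
    from piecewise-linear growth rates anchored at the peak exposure year.
    Inference is by component-wise random-walk Metropolis-Hastings with
    uniform priors, giving posterior medians, credible intervals, and
    forward projections of annual deaths with prediction intervals to 2050.
    Includes a synthetic-data generator (population surfaces and Poisson
    death counts) so the full simulate-fit-diagnose-project pipeline can be
    exercised without access to a national mesothelioma register.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
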