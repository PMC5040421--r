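Package: GeoKrige
Title: Universal and Bayesian Kriging with Optimized Spatial Sampling Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geostatistical prediction of groundwater solute concentrations
    from point-referenced monitoring data. Provides variogram model fitting by
    ordinary and weighted least squares, maximum likelihood and restricted
    maximum likelihood over exponential, Gaussian, spherical and cubic
    families; universal kriging with a polynomial coordinate trend via the
    bordered semivariogram system; Bayesian universal kriging with a discrete
    prior on the relative nugget and range and a noninformative prior on the
    sill, with posterior-predictive simulation and credible intervals;
    leave-one-out cross-validation (RMSPE) for model comparison; and spatial
    simulated annealing for adding or deleting monitoring locations under a
    mean-universal-kriging-variance objective. Includes a Gaussian random
    field simulator and Box-Cox transformation utilities so the full pipeline
    can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), MASS, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'geodata.R'
    'variogram.R'
    'likelihood.R'
    'kriging.R'
    'bayes.R'
    'design.R'
    'synthetic.R'
    'pipeline.R'
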