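Package: carrygoose
Title: Mass-Dependent Carry-Over Effects and Breeding-Season Weather in
    Brent Geese
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for quantifying how pre-migration body mass
    (a carry-over effect) interacts with breeding-season weather (June
    North Atlantic Oscillation) to determine offspring counts in
    light-bellied Brent geese. Provides scaled-mass-index allometric
    standardisation with seasonal correction, polynomial detrending of
    the NAO series, a Poisson random-intercept GLMM engine (Laplace
    approximation), AICc ranking with the nesting rule and model
    averaging (natural and shrinkage estimators, relative importance,
    marginal R squared), Bayesian MCMC refits for prediction with
    credible intervals, a bivariate latent-variable model yielding the
    posterior mass-offspring correlation, and a synthetic-data generator
    reproducing the statistical structure of the field data so the whole
    pipeline is testable without the undeposited observations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
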