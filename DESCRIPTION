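Package: rfdcriteria
Title: QSAR Reference Dose Prediction and Human Health Water Quality Criteria
Version: 0.1.0
Authors@R: person("RfD", "Criteria Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts oral reference doses (RfD) of pesticide-class chemicals
    from molecular descriptor tables via screened forward-backward stepwise
    multiple linear regression on -log10(RfD), validates fitted models with a
    standard QSAR diagnostics suite (adjusted R-squared, RMSEP, Durbin-Watson,
    variance inflation factors, cross-validated q2, origin-regression slopes
    k and k', fold-difference coverage), propagates predicted RfDs into human
    health ambient water quality criteria through trophic-level
    bioaccumulation factors, and classifies monitoring-site hazard quotients
    into risk categories. Includes a synthetic-data generator emulating the
    statistical structure of descriptor matrices and lognormal monitoring
    concentrations, and a scriptable pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
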