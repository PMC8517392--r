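Package: pslwork
Title: Non-Invasive Left Ventricular Pressure-Strain Loop Myocardial Work Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes left ventricular myocardial work indices from segmental
    longitudinal strain traces, brachial cuff blood pressure and valve-event
    timings, using a non-invasively estimated instantaneous left ventricular
    pressure curve (pressure-strain loop method). Provides the global work
    index (GWI), constructive work (GCW), wasted work (GWW), work efficiency
    (GWE) and global longitudinal strain (GLS); a synthetic two-group
    (normal-control versus type 2 diabetes) cohort generator with configurable
    covariate distributions and disease-severity effects; and the clinical
    statistics layer for two-group studies (pooled-variance t, Mann-Whitney U
    with normal approximation, Pearson chi-square, correlation, univariable
    and stepwise multivariable linear regression with standardized
    coefficients, and Bland-Altman agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
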