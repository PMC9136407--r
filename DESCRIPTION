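Package: mbassoc
Title: Multi-Model Multivariable Association Testing for Microbiome Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Per-feature multivariable linear and linear mixed models for
    relative-abundance microbiome data: total-sum-scaling normalisation,
    low-abundance filtering, arcsine square-root transformation,
    fixed- and random-effect model fitting with Benjamini-Hochberg FDR
    control, side-by-side comparison of candidate models over identical
    data, stratified detail views with Welch t-tests, and a seeded
    synthetic longitudinal cohort generator with planted (optionally
    confounded) effects for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
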