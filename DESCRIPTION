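Package: clockbias
Title: Audit Toolkit for Epigenetic Clock Age Prediction Bias
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts DNA methylation (DNAm) age from Illumina-style beta
    value matrices with calibrated linear clock models, and audits the
    systematic old-age underestimation of such clocks: calibration slope
    against the identity line, Bland-Altman agreement summaries, age-binned
    bias, per-locus influence and saturation analytics, and association tests
    of age acceleration with age-correlated phenotypes run with and without
    chronological age as a covariate. Includes a seeded synthetic-cohort
    generator with logit-linear age trajectories and boundary saturation, a
    ridge-trained demonstration clock, and an end-to-end experiment showing
    how age-correlated phenotypes acquire spurious age-acceleration
    associations unless age is covaried.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
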