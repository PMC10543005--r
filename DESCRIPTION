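Package: placebotwin
Title: Twin-Cohort Placebo Analgesia Analysis with Heteroskedastic Mixed
    Models, Neuromarker Scoring and Bayes Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing placebo analgesia in twin cohorts: synthetic
    twin-cohort and trial-table generators with known ground truth, a minimal
    first-level fMRI general linear model (canonical HRF, cosine drift basis,
    frame censoring), multivariate signature and region-of-interest scoring of
    contrast maps, trial- and participant-level quality-control exclusions, a
    zygosity-heteroskedastic repeated-measures linear mixed model estimated by
    REML with Satterthwaite degrees of freedom, Jeffreys-Zellner-Siow Bayes
    factors for nested fixed effects with prior-robustness scans, and
    brain-behaviour, expectation and cross-modality transfer correlation
    models.  All stages run end-to-end on simulated data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
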