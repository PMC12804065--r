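Package: rgpv
Title: Accounting for Rapid Guessing in Plausible Value Estimation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying and correcting the distortion that rapid
    guessing (disengaged, chance-level responding on timed test items)
    introduces into group comparisons based on plausible values. Provides a
    hierarchical mixture simulator for item responses and response times of
    two groups with correlated engagement, ability and speed; response-time
    threshold methods (fixed common-k and antimode-based) with response
    time effort summaries and classification diagnostics; marginal maximum
    likelihood Rasch and latent-regression fitting with effort-moderated
    missing-coding of flagged responses; plausible value drawing; Cohen's d
    and group-moment estimands pooled by Rubin's rules; and a Monte Carlo
    performance harness reporting convergence, bias, empirical standard
    error, mean squared error and coverage with Monte Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Classification
RoxygenNote: 7.3.3
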