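Package: crosstoj
Title: Crossed-Hands Tactile Temporal-Order Judgments: Simulation,
    Behavioural Statistics, and a Hierarchical Bayesian Reference-Frame
    Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing tactile temporal-order-judgment (TOJ)
    experiments in which the hands are crossed over the body midline.
    Provides a generative simulator of the canonical two-posture design
    (upright vs. lying on the side, uncrossed vs. crossed hands, eight
    signed stimulus onset asynchronies), trial-exclusion filters, the
    proportion-correct-difference (PCD) crossed-hands-deficit score with
    its frequentist layer (mixed ANOVA, one-sample t-tests, effect sizes,
    within-subject-corrected error bars), and a hierarchical Bayesian
    model of internal and external reference-frame weights with
    body-posture context multipliers, estimated by a random-walk
    Metropolis-Hastings sampler with split-chain convergence diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
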