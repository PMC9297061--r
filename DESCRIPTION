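Package: metacate
Title: Metalearners for Personalized Optimal Treatment Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates conditional average treatment effects (CATE) for a
    binary lifestyle treatment and converts them into personalized optimal
    decisions that minimize a continuous outcome such as body mass index.
    Implements the T, S and X metalearners together with the hybrid SX and
    SXwint learners, which combine a jointly fitted outcome model with an
    X-style imputation stage on a held-out re-training split. Includes a
    lasso solution-path covariance test for screening features entering the
    outcome model, two-sample Kolmogorov-Smirnov evaluation of the
    personalized-optimal / non-optimal / general-optimal group decomposition,
    a validated reader for lifestyle cohort tables with derived BMI, and a
    synthetic cohort generator with known potential outcomes for testing the
    full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
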