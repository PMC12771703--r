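Package: psamix
Title: Phenotype Stratification of Psoriatic Arthritis by Mixed-Type
    Finite Mixture Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised stratification of psoriatic-arthritis (PsA)
    cohorts into latent clinical phenotypes. Fits finite mixture models to
    mixed-type baseline features (diagonal Gaussian for continuous,
    multinomial for categorical) by expectation-maximisation, selects the
    number of phenotypes by a BIC elbow rule over a grid, and assesses
    cluster stability with Monti consensus subsampling. Includes cohort
    ingestion with missingness and collinearity screening, per-phenotype
    descriptive profiling, responder-endpoint computation (MDA, DAPSA low
    disease activity, ACR50, joint-count improvement, MCIDs) under
    as-observed and non-responder-imputation-with-multiple-imputation
    analyses, and a synthetic cohort generator emulating the latent
    phenotype structure of a biologic-naive PsA trial population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
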