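Package: edrisk
Title: Admission-Risk Stratification of Emergency Department Diagnosis Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies ambulatory emergency department (ED) presentations by
    hospital-admission risk using their primary ICD-10 diagnosis codes.
    Computes per-code admission risks, clusters them with one-dimensional
    k-means (with an exact dynamic-programming oracle and gap-statistic,
    silhouette, Calinski-Harabasz and Davies-Bouldin model selection),
    aggregates codes into WHO ICD-10 blocks with cumulative-coverage
    reduction and dominant-block identification, and quantifies the
    association between presentation characteristics and risk-cluster
    membership with a proportional-odds ordinal regression. Includes a
    synthetic ED-registry generator with a multi-tier latent risk structure,
    Zipf-like code frequencies and configurable covariate effects, so the
    whole pipeline is testable without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust,
    cluster
Config/testthat/edition: 3
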