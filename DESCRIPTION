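Package: synthcohort
Title: Artificial Patient Cohorts from a Geometry-Based Variational Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates artificial patient cohorts from small, high-dimensional
    clinical tables and audits how trustworthy they are. Mixed-type cohorts
    (numerical, binary, categorical columns) are encoded to a fully numeric
    design matrix, a variational autoencoder with a learned Riemannian latent
    metric is trained on it, and new patients are sampled by a volume-weighted
    random walk over the learned metric and decoded back to schema-valid
    records. Audit tools score fidelity (per-variable distribution stability
    and correlation stability), confidentiality (filter similarity and
    nearest-neighbour degree of anonymization), and plausibility (Cohen's
    kappa for blinded expert categorization tasks).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
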