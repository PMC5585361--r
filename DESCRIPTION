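Package: pdcscreen
Title: Phenotypic Drug-Screen and Model-Concordance Analytics for
    Patient-Derived Cultures and Xenografts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for phenotypic drug screens on
    patient-derived primary cultures (PDC) and validation in
    patient-derived xenografts (PDX). Implements plate-level inhibition
    scoring against DMSO controls, Z-score based selective-toxicity hit
    calling for dual-fluorescence co-culture screens, four-parameter
    logistic dose-response fitting with above-range IC50 censoring,
    expression-matrix quantile normalization with fold-change selection
    and Fisher gene-set overrepresentation, and xenograft tumour-growth
    metrics (ellipsoidal volumes, tumour-growth-inhibition ratios,
    endpoint t-tests). Ships seeded synthetic-data generators with
    planted ground truth for every input type so the full pipeline can
    be exercised and benchmarked end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
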