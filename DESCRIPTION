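Package: uricad
Title: Urinary Metabolomics Analysis of Incident Coronary Artery Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for prospective urinary NMR metabolomics of
    incident coronary artery disease in type 1 diabetes. Provides
    preprocessing of metabolite panels (half-minimum zero replacement,
    creatinine normalization, skewness-guided log/sqrt transforms,
    standardization), metabolome-wide Cox proportional-hazards screening
    with a PCA-derived effective number of tests, mixed-type correlation
    networks with a permutation-based case-to-control difference network,
    bagged support-vector-machine metabolomic state profiling, and a
    synthetic cohort generator that emulates the data structure the
    analyses assume so every stage is testable without access to
    individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    igraph,
    e1071,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
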