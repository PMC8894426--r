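Package: metabophen
Title: Phenotype Discrimination from Two-Matrix Untargeted Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discriminating clinical phenotype groups
    from untargeted metabolomics measured in two paired matrices (cell
    pellets and their spent growth media), as used to contrast germline
    PTEN mutation carriers presenting with autism/developmental delay
    versus cancer. Implements batch median-scaling normalization with
    minimum-value imputation and protein normalization, covariate-adjusted
    differential abundance with empirical-Bayes variance moderation,
    cells-over-media and pairwise metabolite-ratio (metabotype) feature
    construction, correlation-block and correlation-distance clustering
    analyses, and leave-one-out cross-validated LogitBoost classification
    with three feature-reduction variants. A synthetic-cohort generator
    with planted effects makes every stage testable without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
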