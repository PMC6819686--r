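Package: sgeblup
Title: Single-Step Genomic Evaluation with Social Genetic Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed-model machinery for genetic evaluation of socially
    affected traits (average daily gain of group-housed pigs) under direct
    plus social (indirect) genetic effects. Builds pedigree numerator
    relationship matrices and their sparse inverses, VanRaden genomic
    relationship matrices with quality control and blending, and the
    tuned single-step H inverse; estimates direct/social genetic
    (co)variances together with litter and pen variances by average-
    information REML; computes total breeding values, total heritability,
    prediction-error-variance accuracies and forward cross-validation
    correlations; and simulates pen-structured populations with known
    ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
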