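Package: qsrrflow
Title: Automated QSRR Model Building for Retention-Time Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantitative structure-retention relationship (QSRR)
    modelling for liquid-chromatography retention-time prediction in
    lipidomics and metabolomics. Reads compound tables (name, SMILES,
    retention time), computes 2-D molecular descriptors, applies
    descriptor-hygiene filters (near-constant, high-missing, inter-descriptor
    correlation), selects features by recursive feature elimination with a
    random-forest regressor, chooses among linear, random-forest and
    RBF-kernel support-vector regression by nested cross-validation, and
    persists self-contained models for later prediction with extrapolation
    flagging. Includes the randomized train/test split study protocol,
    evaluation statistics (best-fit line, r-squared, median error, tolerance
    bands, a relative-error validity filter) and seeded synthetic-data
    generators for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ranger,
    e1071,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
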