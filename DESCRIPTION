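Package: kdn
Title: Oncogene-Dosage Stratification and Niche Readouts for Single-Cell Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, seed-reproducible pipeline for stratifying single
    cells by the expression of a single oncogenic transgene (KRAS-G12D dosage
    groups low/intermediate/high), learning a small multilayer-perceptron
    classifier of group identity and extracting its top predictive genes,
    projecting external tumor cohorts into the same groups with
    tumor-microenvironment composition readouts, scoring gene modules with an
    expression-matched control construction and a highest-score-above-mean
    signature assignment rule, quantifying in-situ transcript spots per
    marker-positive cell on multi-channel fluorescence images, and computing
    grade-stratified nonparametric statistics for a cyst-fluid biomarker
    cohort. Ships seeded synthetic-data generators with planted ground truth
    for every input the pipeline consumes, including probe-level count
    matrices with unequal per-probe efficiency and the bespoke probe QC and
    aggregation rules they require.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    EBImage,
    class,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
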