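Package: ifnmono
Title: Type I Interferon Stratification and Single-Cell qPCR Analysis of
    Monocytes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-cell qPCR studies of monocyte
    subsets in rheumatoid arthritis patients stratified by serum type I
    interferon activity. Implements reporter-assay scoring of serum IFN
    activity with IFN-beta/alpha ratio patient grouping, quality control
    of single-cell Ct matrices (well flags and panel-wide failure scores),
    per-gene expressed/not-expressed and quantitative group comparisons
    with a correlation-adjusted Bonferroni correction, detection of
    subject-level on/off transcript states, and multivariate summaries
    (PCA, hierarchical clustering, logistic models with ROC). A seeded
    synthetic-cohort generator emulates the data structure the analysis
    assumes, for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    rlang,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
biocViews: SingleCell, GeneExpression, QualityControl, ImmunoOncology
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
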