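Package: metamarker
Title: Cross-Platform Microarray Meta-Analysis for Single-Gene Tumor Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multi-study microarray meta-analysis aimed at
    discovering and validating compact diagnostic gene signatures, motivated by
    the discrimination of papillary thyroid carcinoma from benign thyroid
    nodules. Probes are matched across platforms by identical RefSeq annotation
    sets, studies are merged and quantile normalised collectively, dataset bias
    is removed by Distance Weighted Discrimination (DWD), classification uses
    nearest shrunken centroids with leave-one-out cross-validation, and
    inference uses empirical-Bayes moderated t-statistics with a competitive
    accumulated-t gene-set test. An independent validation arm covers RT-qPCR
    data: geNorm reference-gene stability, relative quantification, ROC-based
    decision thresholds and confusion metrics. A seeded synthetic multi-study
    generator emulates the statistical structure the analysis assumes, so the
    whole pipeline is exercisable and testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
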