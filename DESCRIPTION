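Package: protsel
Title: Candidate Biomarker Selection from Label-Free Spectral-Count Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative feature-selection pipeline for label-free
    spectral-count proteomics with multi-class sample designs. Provides a
    beta-binomial likelihood-ratio test for differential protein abundance,
    nearest shrunken centroids and linear SVM recursive feature elimination
    classifiers, a double (nested) cross-validation engine that tunes each
    method and estimates prediction error on held-out samples, concordance
    analysis of ranked candidate lists (Jaccard curves, three-way Venn
    partitions), and clustering diagnostics (hierarchical clustering,
    neighbor-joining trees, silhouette coefficients) before and after
    feature selection. Includes a synthetic spectral-count generator with
    planted class effects and overdispersion so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    e1071,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
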