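Package: boldmvpa
Title: Voxel-Wise Resting-State fMRI Feature Extraction and MVPA Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-measure voxel-wise analysis of resting-state BOLD fMRI for
    two-group discrimination (e.g. Alzheimer's disease or mild cognitive
    impairment versus controls). Computes regional homogeneity (Kendall's W),
    amplitude of low-frequency fluctuation (ALFF) and its fractional variant,
    weighted degree centrality, and seed-based functional connectivity maps;
    reduces features by two-sample t maps with Monte-Carlo cluster-extent
    correction followed by SVM recursive feature elimination or LASSO; and
    classifies with an extreme learning machine or support vector machines
    under leave-one-out or k-fold cross-validation with permutation
    significance testing. Includes a synthetic BOLD cohort generator with
    planted coherence, amplitude and coupling effects over AR(1) noise so the
    full pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    e1071,
    igraph,
    generics,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
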