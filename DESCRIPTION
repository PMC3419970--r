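Package: adhdml
Title: Multi-Site Multimodal Imaging Classification of ADHD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, site-aware machine-learning pipeline for
    diagnostic classification of attention deficit hyperactivity disorder
    (ADHD) from multimodal neuroimaging and demographic features. Implements
    functional feature extraction from resting-state time series
    (Fisher-z Pearson connectivity matrices, nodal power spectra, voxelwise
    global connectivity, voxelwise regional homogeneity via Kendall's W),
    graph-theoretical network metrics averaged across proportional sparsity
    thresholds with random-network normalization, multiple SVM recursive
    feature elimination (mSVM-RFE) for feature ranking, externally
    cross-validated feature-subset selection with nested RBF-SVM
    hyperparameter tuning, per-site classifiers with cross-site mean
    alignment for sites lacking labeled training data, modality-level
    majority voting with site-specific subtype assignment, and competition
    style scoring. A synthetic multi-site cohort generator reproduces the
    statistical structure the analysis assumes, so the whole pipeline can be
    exercised and tested without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
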