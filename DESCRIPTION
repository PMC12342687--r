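Package: ecgphenomap
Title: ECG-Based Phenogrouping of HFpEF Patients with Dynamic Time Warping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised phenomapping of heart failure with preserved
    ejection fraction (HFpEF) cohorts from lead-II electrocardiograms.
    Implements a from-scratch dynamic time warping (DTW) distance with
    Ward hierarchical clustering on raw waveforms, k-means clustering on
    extracted ECG feature tables, a minimal PR-interval/QRS-duration
    feature set chosen by a three-method consensus (resampled PCA, L1
    logistic regression, one-tailed t-tests), and a creatinine-based
    baseline partition for cardiorenal (CKD) risk stratification.
    Partitions are compared with co-cluster Jaccard, Rand and adjusted
    Rand indices, silhouette scores, bootstrap stability, and per-cluster
    ANOVA enrichment. A synthetic-cohort generator with planted
    phenogroup morphologies makes the whole pipeline testable without
    access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    cluster,
    parallel,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
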