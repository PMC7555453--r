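Package: tagprint
Title: Triacylglycerol Fingerprint Chemometrics for Meat Species
    Authentication
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for authenticating beef, pork and chicken in meat and
    meat products from ambient high-resolution mass-spectrometry (DART-HRMS)
    triacylglycerol (TAG) fingerprints. Provides accurate-mass annotation of
    ammonium-adduct TAG ions against a curated marker library, constant
    row-sum normalization and Pareto scaling, PCA and NIPALS PLS-DA with
    cross-validated Q2, recognition/prediction ability, permutation testing,
    VIP scores and S-plot marker selection, Hotelling T2 screening of
    suspicious products, admixture detection-limit estimation, a synthetic
    fingerprint generator with QC-pool acquisition sequences, and a
    declared-composition versus PCR-call label-compliance checker.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
biocViews: MassSpectrometry, Metabolomics, Lipidomics, Classification,
    QualityControl
RoxygenNote: 7.3.3
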