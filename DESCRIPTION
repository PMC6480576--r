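Package: DATspect
Title: Striatal Dopamine Transporter SPECT Quantification and Stage
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies dopamine transporter (DAT) SPECT brain volumes for
    Parkinson's disease staging. Implements whole-brain single-threshold
    segmentation, 3D seed region growing of the striatal activity region,
    six histogram and volume features (skewness, kurtosis, Cyhelsky's
    skewness coefficient, Pearson's median skewness, DAT activity volume
    and maximum), nonparametric group statistics (Mann-Whitney U,
    Kruskal-Wallis, Dunn-Bonferroni), and three-group logistic-regression
    and RBF-SVM classifiers with a full validity panel (sensitivity,
    specificity, PPV, NPV, accuracy, AUC, Cohen's kappa). A digital
    striatal phantom generator with stage-dependent uptake, Poisson
    counting noise and reconstruction blur makes the whole pipeline
    testable without patient data.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    S4Vectors,
    SummarizedExperiment,
    nnet,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'volume-io.R'
    'phantom.R'
    'segmentation.R'
    'features.R'
    'group-stats.R'
    'classification.R'
    'pipeline.R'
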