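Package: hspkit
Title: Hierarchical Prediction of Heat Shock Proteins from Sequence Composition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for predicting heat shock proteins (HSPs), their six
    chaperone families (HSP20/40/60/70/90/100) and the four DnaJ (HSP40)
    sub-types from protein sequence alone. Encodes sequences into g-spaced
    amino-acid pair compositions (GPC), pseudo amino-acid composition (PAAC),
    composition-transition-distribution (CTD) and property autocorrelation
    (ACF) descriptors; ranks features by five selection techniques; trains
    kernel support-vector machines and composes them into a three-stage
    hierarchical predictor; and evaluates with stratified k-fold and
    leave-one-out cross-validation, balanced resampling, one-vs-rest family
    protocols, ROC/PR areas and Matthews correlation. Includes a synthetic
    sequence generator that plants gapped-pair compositional signal for
    controlled benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    seqinr,
    e1071,
    glmnet,
    ranger,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
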