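Package: mras
Title: Multi-Layer Resource Allocation with Sequence Kernels for
    ncRNA-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts associations between non-coding RNAs and diseases by
    propagating resource through a disease-target-ncRNA tripartite network.
    Each propagation layer is reweighted by RBF-kernel similarity computed
    from l-gram (spectrum) features of target and ncRNA sequences.  Includes
    readers for FASTA and edge-list inputs, network degree statistics, a
    link-cut 5-fold cross-validation protocol with ROC/AUC scoring, a
    sigma-grid search for the kernel bandwidths, and a synthetic-data
    generator with a plantable sequence/topology signal for end-to-end
    testing without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
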