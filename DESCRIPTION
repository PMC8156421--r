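Package: drivernb
Title: Driver Mutation Classification from Nucleotide Neighborhood Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Represents the raw nucleotide neighborhood of somatic point
    mutations as k-mer count, TF-IDF or one-hot features, quantifies the
    divergence between driver and passenger neighborhood distributions with
    class-conditional Gaussian kernel density estimates and a randomized
    Jensen-Shannon null, and trains driver-versus-passenger classifiers,
    including a generative KDE classifier and soft-voting ensembles, with
    repeated stratified cross-validation, repeated edited nearest neighbors
    undersampling, impurity-based feature selection, decision-threshold
    search and a composite-score metric protocol.  A synthetic-data module
    generates toy genomes and class-labeled mutations with controllable
    neighborhood-context divergence so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    graphics,
    grDevices,
    methods,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
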