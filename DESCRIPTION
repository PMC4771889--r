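Package: csfpa
Title: Gene Regulatory Network Inference with a Cuckoo Search-Flower
    Pollination Hybrid over Recurrent Neural Network Gene Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reverse engineering of gene regulatory networks from
    time-series expression data using a decoupled discrete-time
    recurrent neural network (RNN) gene model. Per-gene RNN parameters
    (regulatory weights, basal bias, time constant) are fitted by a
    Flower Pollination Algorithm, while an outer Cuckoo Search with
    Levy-flight moves selects the sparse set of candidate regulators
    for each target gene. Includes the 30-gene artificial benchmark
    network generator, noise injection, confusion-matrix evaluation
    (sensitivity, specificity, accuracy, Matthews correlation
    coefficient), and readers/writers for expression matrices and
    signed adjacency networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: NetworkInference, GeneRegulation, TimeCourse, Network
RoxygenNote: 7.3.3
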