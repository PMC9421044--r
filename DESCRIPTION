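Package: ribocleave
Title: Ribozyme Fitness Landscapes from Self-Cleavage Sequencing Data
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing deep mutational scanning experiments on
    self-cleaving ribozymes. Estimates per-variant catalytic activity
    (fraction cleaved) from co-transcriptional cleavage sequencing reads,
    quantifies pairwise epistasis, builds genotype (Hamming) networks, and
    predicts the activity of higher-order mutants with random-forest and
    LSTM-feature-hybrid regressors under mutational-distance train/test
    designs. Includes a fully seeded synthetic-data generator (doped mutant
    libraries, ground-truth activity landscapes with compensatory base-pair
    epistasis, simulated cleavage reads) so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite,
    ranger,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
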