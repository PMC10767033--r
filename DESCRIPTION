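Package: quboseq
Title: Multi-Objective Antibody Sequence Design with Ensemble Predictors
    and QUBO Annealing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs short protein sequences (antibody CDR libraries and
    similar fixed-length regions) by multi-objective black-box
    optimization. Phage-display count tables from two pools are turned
    into enrichment scores and a labeled training set; an ensemble of
    sequence-activity classifiers trained on subsampled splits supplies
    a mean-activity objective and a prediction-instability objective; a
    binary autoencoder maps sequences to bit vectors where a
    factorization-machine surrogate is compiled to a QUBO and sampled by
    simulated annealing. Pareto-front and hypervolume machinery track
    progress, and selection filters with novelty (Hamming distance)
    reporting produce a ranked candidate list. Includes a synthetic
    motif-landscape generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
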