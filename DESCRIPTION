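Package: EmbedRank
Title: Few-Shot Fitness Regression and Ranking of Enzyme Homologs from
    Sequence Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritises candidate enzymes from homology searches when only a
    handful of experimental measurements (for example catalytic efficiency
    kcat/KM) are available. Protein sequences are turned into fixed-size
    vectors by mean-pooling per-residue representations of a pluggable
    embedder backend, with per-layer selection by cross-validation;
    k-nearest-neighbour, support-vector and random-forest regressors are
    tuned by grid search and used to rank candidate homologs by predicted
    fitness. Includes E-value and bidirectional-coverage filtering of
    tabular (BLAST outfmt-6 style) homology hits, greedy identity-based
    redundancy removal via global alignment, a subsampling protocol for
    assessing how much labelled data a task needs, and a deterministic
    synthetic fitness-landscape generator with a surrogate embedder so the
    whole workflow is testable without model downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    e1071,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
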