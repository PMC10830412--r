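Package: enforge
Title: Design of Tissue-Specific Synthetic Enhancers by Deep and Transfer Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts tissue-specific enhancer activity from DNA sequence and
    designs synthetic tissue-specific enhancers de novo. Convolutional neural
    networks are first trained to regress chromatin accessibility from
    1,001-bp genomic windows under a chromosome-half hold-out cross-validation
    scheme, then fine-tuned by transfer learning into binary activity
    classifiers on small in-vivo enhancer collections. Trained models are
    interpreted with per-nucleotide contribution scores against
    dinucleotide-shuffled references and used to screen random sequences for
    candidates that are predicted to be accessible and active specifically in
    a target tissue. A synthetic-genome generator with planted motifs and a
    known activity rule makes the whole pipeline runnable and testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    withr,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    caret
Config/testthat/edition: 3
RoxygenNote: 7.3.3
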