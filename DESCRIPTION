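Package: forktrace
Title: Single-Molecule Replication Fork Mapping from Nanopore Base-Analogue Signals
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects the thymidine analogue BrdU in (simulated) nanopore
    raw-current reads with single-nucleotide resolution and interprets the
    per-molecule BrdU pattern into leftward- and rightward-moving replication
    fork probabilities, replication origin calls and termination-site calls.
    The pipeline couples a banded hidden Markov signal-to-reference alignment
    with a small residual convolutional network for per-thymidine BrdU
    probabilities, and a convolutional encoder-decoder that labels fork
    direction along each read. A synthetic-signal generator built on a 6-mer
    pore model with analogue-shifted current levels provides ground truth for
    training and evaluation, emulating uniform-substitution, primer-extension,
    G1-release and pulse-chase experimental designs. Outputs are written as
    easy-to-parse tables, BED and bedgraph tracks for genome-browser
    visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings,
    Rsamtools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
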