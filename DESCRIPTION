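Package: epifill
Title: Markov Models, MAP Decoding and Threshold Filling for Histone
    Modification Inheritance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the inheritance of histone modification patterns through
    DNA replication as a communication channel. Parental modification
    sequences follow a two-parameter first-order Markov chain; replication
    randomly erases marks with a per-nucleosome retention probability
    (default one half). The package reconstructs mother-like sequences from
    daughter sequences by exact sequence maximum-a-posteriori (Viterbi
    trellis) decoding and by the enzyme-implementable threshold-k gap-filling
    rule derived from it, classifies the (alpha, beta) parameter space by
    which rule is optimal, and quantifies reconstruction fidelity (bit and
    block error rates) across parameter regimes, generations and pairs of
    antagonistic modifications. Includes tools to binarize population-
    averaged occupancy tracks into single-cell-like realizations and to
    estimate chain parameters from data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
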