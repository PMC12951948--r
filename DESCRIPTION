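Package: ansscore
Title: Adjusted Neighborhood Scoring for Gene Signatures in Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene signature scoring for single-cell RNA-seq with Adjusted
    Neighborhood Scoring (ANS), a deterministic variant of Tirosh-style
    control-based scoring in which each signature gene receives the contiguous
    window of control genes whose average expression best matches its own.
    Also provides the classic bin-based control strategies (sampled, all-genes,
    least-variable), the rank-based scorers UCell and JASMINE, score-based
    (argmax) cell-type and cell-state annotation with balanced-accuracy,
    information-quantity and scale-imbalance metrics, benchmark procedures for
    control-gene bias, batch robustness, signature length and signature noise,
    and a synthetic scRNA-seq generator with known cell types, markers,
    dropout and batch structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    nnet,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
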