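Package: cbnpa
Title: Network Perturbation Amplitude Scoring on Causal Biological Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Compiles causal biological network models written in a restricted
    subset of the Biological Expression Language (BEL 1.0) into two-layer
    models (a signed causal backbone plus downstream edges to measurable
    transcripts), scores differential gene-expression contrasts onto them with
    the network perturbation amplitude (NPA), assesses score specificity with
    "O" and "K" permutation statistics, and decomposes the score into leading
    nodes. Includes a synthetic-data generator with known ground truth for
    calibration, power and parameter-recovery studies, and a small command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
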