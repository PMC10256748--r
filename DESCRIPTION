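Package: contiseg
Title: Continual Learning Strategies for Semantic Segmentation of Biomedical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Desk-scale toolkit for studying catastrophic forgetting in
    sequential (continual) training of segmentation networks. Provides a
    seeded generator of domain-shifted synthetic segmentation tasks with
    heterogeneous label schemes, label-scheme alignment, a compact
    encoder-decoder segmentation network with an explicit body/head split
    and multi-head bookkeeping, five continual-learning strategies
    (rehearsal, elastic weight consolidation, learning without forgetting,
    Riemannian walk, and background-modelling distillation) over a common
    training loop, and continual evaluation metrics: Dice, backward and
    forward transfer, inter-task matrices and multi-validation-set
    trajectories. Tasks round-trip through NIfTI volumes with JSON
    manifests so real volumetric datasets plug in identically.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
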