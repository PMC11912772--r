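Package: stsimeval
Title: Benchmarking Toolkit for Spatial Transcriptomics Simulators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies how faithfully a simulated spatial transcriptomics
    dataset reproduces a reference dataset. Computes spot-level, gene-level
    and spatial-level data-property samples, compares real versus simulated
    distributions with a two-sample kernel density statistic, evaluates four
    downstream analysis tasks (spatial clustering, cell-type deconvolution,
    spatially variable gene detection, spatial cross-correlation), and
    aggregates results into rank-based overall scores. Includes a
    cluster-then-simulate adaptor that lets any count simulator produce
    spatially structured data, a self-contained negative-binomial reference
    simulator, and a synthetic-fixture generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    pracma,
    stats,
    utils
Suggests:
    edgeR,
    igraph,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
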