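Package: spineglia
Title: Microglia-Spine Interaction Scoring, Calcium Response Pipelines, and
    Hierarchical Bootstrap Inference for Adult-Born Neuron Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify interactions between microglial processes and
    dendritic spines from two-channel time-lapse imaging, scored against a
    chance null built by circularly translating the microglia channel; a
    quality-controlled delta-F over F-sigma pipeline for trial-structured
    two-photon calcium traces with ROC threshold selection, effective-odor
    counts, lifetime sparseness, event detection, and a principal-angle
    permutation test on response time courses; spine morphometry
    classification and density summaries from Imaris-style exports;
    voltage-clamp sweep quality control and passive membrane property
    estimation from test pulses; and two-level hierarchical bootstrap
    inference for nested measurements (mice over dendrites, dendrites over
    spines, cells over synaptic events). Seeded synthetic-data generators
    with known ground truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    tools,
    utils
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
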