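Package: cgcn
Title: Connectivity-Based Graph Convolutional Networks for Frame-Wise fMRI Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds k-nearest-neighbor graphs from group functional-connectivity
    matrices and classifies ROI-level fMRI time series frame by frame with a
    connectivity-based graph convolutional network (cGCN). Node signals are
    convolved over connectomic (not Euclidean) neighborhoods with an asymmetric
    EdgeConv edge function and feature-wise max aggregation, pooled over nodes
    and time, and passed to a softmax classifier. Includes the full training
    protocol (Adam, stepwise learning-rate decay, best-validation
    checkpointing, L2 sweep), leave-one-site-out and stratified k-fold
    cross-validation harnesses, a random-graph control, single-ROI occlusion
    saliency, and a synthetic multi-subject cohort generator with planted
    connectivity fingerprints, group effects, and site effects.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
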