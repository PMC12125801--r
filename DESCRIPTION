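Package: msaunet
Title: Multi-Scale Spatial Attention U-Net for Small-Organ CT Segmentation
Version: 0.1.0
Authors@R:
    person("MSAU-Net", "Maintainers", email = "msaunet@example.org", role = c("aut", "cre"))
Description: Tools for segmenting small, irregular, low-contrast organs (the
    gallbladder regime) in 2-D CT slices. Implements a U-Net backbone
    augmented with Multi-Spatial-Attention (MSA) blocks, built from a
    multi-scale feature extraction and fusion module (MSFEF) and a
    multi-scale spatial attention module (MSSA) extending
    channel-squeeze/spatial-excitation (sSE) gating. Includes a seeded
    synthetic CT phantom generator, Hounsfield-unit preprocessing
    (windowing, CLAHE, geometric augmentation), a Dice loss, a seven-metric
    evaluation suite (DSC, JSC, PPV, SE, Hausdorff distance, RVD, VOE),
    one-way ANOVA with Fisher LSD post-hoc comparisons, and an end-to-end
    training/evaluation pipeline with a command-line entry point. The
    network runs on a small built-in reverse-mode autodiff engine with
    Rcpp-accelerated convolutions; no external deep-learning framework is
    required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    png,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
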