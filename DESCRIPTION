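Package: ecscore
Title: Explainability Consistency Score for Lesion-Annotated Retinal Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the agreement between model-attribution heatmaps and
    expert pixel-level lesion segmentations of fundus photographs using the
    Explainability Consistency Score (ECS): both maps are discretized onto an
    S x S grid (expert lesion pixels weighted inversely to their corpus
    frequency so that rare but diagnostically critical lesions such as
    microaneurysms contribute), and the score is the fraction of shared top-K
    grid cells, normalized by min(K, number of nonzero expert cells).
    Includes architecture-independent saliency methods (Gradients,
    Input x Gradient, Integrated Gradients, SmoothGrad, SmoothGrad-Squared,
    VarGrad) over a pluggable gradient provider, a random-importance
    baseline, percentile-bootstrap confidence intervals, severity-class
    stratification, grid/K sensitivity sweeps, and a synthetic generator of
    lesion mask sets and heatmaps with controllable top-K agreement, so the
    whole framework is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
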