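Package: scafdl
Title: Self-Supervised Diffusion-Based Fracture Detection and Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage, self-supervised framework for detecting and
    localizing fracture-like anomalies in grayscale radiograph crops.
    Stage I synthesizes pseudofracture training pairs by embedding
    foreground-constrained polyline anomalies with texture blending into
    healthy images. Stage II reconstructs a healthy version of each image
    with a denoising diffusion probabilistic model whose one-step
    reconstruction is guided by predictions at multiple time steps
    (improved normal-image guidance). Stage III maps the (input,
    reconstruction) pair to a per-pixel saliency map with a
    squeeze-and-excitation U-Net trained under a smooth-L1 plus focal
    loss. The package ships a seeded phantom-radiograph generator so the
    whole pipeline is testable without clinical data, and an evaluation
    suite with image AUROC, pixel AUROC, and the capped-FPR per-region
    overlap (PRO) score. Networks are implemented natively via
    RcppArmadillo; no external deep-learning runtime is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
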