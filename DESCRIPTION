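Package: caedge
Title: Cellular Automaton Edge Detection Tuned by Particle Swarm Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised edge detection for grayscale (e.g. medical) images using
    a two-step cellular automaton transition rule over the radius-1 Moore
    neighborhood: a 9-bit linear rule selects contributing neighbors, an
    edge-membership ratio maps the local absolute-difference sum to [0,1], and
    a threshold yields the binary edge state. The rule triplet (delta, tau,
    rule) is optimized against ground-truth edge maps by particle swarm
    optimization with Dice-coefficient fitness, supporting per-image and
    batched protocols with global-best resets. Includes Gaussian
    pre-filtering, edge thinning and disconnected-edge removal, a Canny
    baseline, PSNR/SSIM/SNR/gradient-difficulty metrics, a seeded synthetic
    circle-phantom generator with ground-truth boundaries, and experiment
    drivers for noise-robustness, smoothing, batch-size and difficulty
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
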