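Package: cbctgan
Title: Unpaired CBCT-to-Synthetic-CT Translation with a Vision-Transformer CycleGAN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Synthesizes CT-like images from cone-beam CT (CBCT) slices with an
    unpaired cycle-consistent adversarial model whose generators are U-nets with
    a vision-transformer bottleneck (Fourier positional token embeddings, rezero
    residual scaling, and a depth-wise-convolution feed-forward network).
    Includes the full loss family (least-squares adversarial, cycle, identity,
    gamma-centered gradient penalty, and low-pass pixel-wise consistency), the
    5:1 generator/discriminator update schedule, MAE/PSNR/SSIM evaluation with
    body-mask support, a seeded synthetic CT/CBCT phantom generator so the whole
    pipeline is exercisable without clinical data, and a command-line front end.
    Networks are trained with a small built-in reverse-mode autodiff engine
    backed by C++ convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    RNifti,
    EBImage,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
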