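Package: demun
Title: Deep Memory Unrolled Networks for Compressive Image Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for reconstructing images from compressive linear
    measurements y = A x + w with deep unrolled networks. Implements the
    measurement operators (dense Gaussian and undersampled 2D-DCT with exact
    adjoints), DnCNN projectors with end-to-end backpropagation, four
    unrolling schemes (projected gradient descent, Nesterov acceleration,
    approximate message passing, and deep-memory updates that learn a
    coefficient for every past gradient), the last-layer, weighted
    intermediate and skip-layer training losses, PSNR and SSIM evaluation,
    seeded synthetic image generators, and an ablation harness over the
    design grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    png,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
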