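Package: ffasr
Title: Example-Based Super-Resolution for Fundus Fluorescein Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Patch-based single-image super-resolution (SISR) toolkit for
    fundus fluorescein angiography (FFA) and other single-channel retinal
    images.  Trains example-based SR models on high-/low-resolution image
    pairs produced by a bicubic degradation model and reconstructs
    high-resolution images from low-resolution inputs.  Implements
    neighborhood embedding (least-squares and non-negative least-squares
    weights), coupled sparse dictionaries (joint L1 training and
    K-SVD/orthogonal matching pursuit), anchored neighborhood regression
    (ANR and A+), jointly optimized regressors, and super-resolution
    forests, together with PSNR/SSIM evaluation, a synthetic fundus
    phantom generator with grouped homologous images, and an end-to-end
    benchmark pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
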