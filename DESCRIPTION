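Package: aladenoise
Title: Adaptive Local Averaging Denoising for Real-World Camera Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-step denoising of 8-bit real-world camera images. The first
    stage applies an adaptive local averaging (ALA) filter to the luminance
    (Y) channel of the YUV-decomposed image: around every pixel a quadratic
    patch grows until the local brightness variability exceeds a single
    global threshold derived from the image's median brightness and a
    Laplacian-based noise estimate, and the pixel is replaced by the mean of
    the largest admissible patch. The second stage restores sharpness with a
    Gaussian unsharp mask. The package also provides the evaluation metrics
    used to benchmark such filters (pairwise and single-image PSNR, SSIM,
    brightness conservation), seam-free tiled processing with halo overlap
    for multi-core execution, a synthetic fixture generator emulating
    sensor noise and frame-averaged ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
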