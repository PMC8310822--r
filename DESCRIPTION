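Package: ldctbench
Title: Low-Dose CT Noise Simulation and Denoising Benchmark
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates dose-reduced computed tomography images by adding
    Poisson-statistics noise spectrally shaped by a scanner modulation
    transfer function, and benchmarks classical image-space denoisers
    (median, Gaussian, adaptive Wiener) against a residual-learning
    convolutional network with a transfer-learning protocol. Includes a
    synthetic abdominal phantom generator, SSIM/PSNR/MSE image-quality
    metrics with paired significance testing, 16-bit PNG/TIFF and
    single-frame DICOM input, and a command-line benchmark pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
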