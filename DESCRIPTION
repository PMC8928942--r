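Package: cryoalign2d
Title: Frequency-Domain Alignment and Spectral Class Averaging for
    Cryo-EM Particle Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rotational and translational alignment of square particle
    images by cross-correlation in the Fourier domain, with 2D spline
    interpolation of the correlation peak for subpixel and subangle
    estimates, and an iterative joint alignment loop. Includes a 2D
    classification pipeline that builds a pairwise similarity matrix from
    aligned images, constructs a shared-nearest-neighbor graph, partitions
    it with normalized spectral clustering, and produces
    similarity-weighted class averages. Ships seeded generators for
    structured phantom images, analytic Gaussian-mixture projection
    stacks, an additive Gaussian noise model at prescribed
    signal-to-noise ratio, and a reader/writer for MRC/MRCS particle
    stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
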