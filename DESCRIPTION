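Package: quatst
Title: Quaternion Representation and Hypercomplex Fourier Analysis of
    Spatial Transcriptomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps spatial transcriptomics count data to quaternions
    (sequencing depth as the real part, the unit-length relative
    expression direction as the vector part), assembles quaternion-valued
    tissue rasters, and analyses them with rotation quaternions, a
    two-dimensional quaternion-domain discrete Fourier transform realized
    by Cayley-Dickson decomposition into two complex FFTs, spectral
    filtering, real-mask convolution and quaternion biconvolution, and
    false-colour RGBA rendering. Includes synthetic data generators for
    multi-population count data and spatially structured expression
    domains, plus a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    grDevices,
    jsonlite,
    png,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
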