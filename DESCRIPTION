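Package: visaniso
Title: Anisotropic Gaussian Smoothing Models of Perceived Orientation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models visual orientation anisotropy as anisotropic Gaussian
    scale-space smoothing of the retinal image. Provides elliptical Gaussian
    luminance-profile (GLP) stimuli and elliptical smoothing kernels,
    closed-form prediction of illusory orientation biases by covariance
    addition, a numeric convolution oracle based on image second moments,
    a seeded simulator of the psychophysical adjustment experiment, and
    weighted least-squares fitting with nested F-test comparison of
    isotropic, homogeneous, radial-heterogeneous and angular-heterogeneous
    smoothing models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
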