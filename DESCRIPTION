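Package: sfdmueller
Title: Spatial Frequency Domain Mueller Matrix Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and data reduction for spatial frequency
    domain (SFD) Mueller matrix imaging. Provides Mueller/Stokes algebra
    (Cloude covariance realizability, polarimetric purity indices,
    Lu-Chipman polar decomposition), a model of a 16-state dual
    liquid-crystal polarimeter with data-reduction matrices, complex-valued
    demodulation of sinusoidally structured illumination, phase
    normalization and BRDF scaling against diffuse and specular references,
    and an analytic scattering-kernel scene simulator that serves as the
    oracle for the whole pipeline.
License: MIT
Encoding: UTF-8
Imports: jsonlite, tiff, png, optparse, stats, graphics, grDevices, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
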