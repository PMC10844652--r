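Package: pawave
Title: Wave-Based Photoacoustic Imaging Through Thick Aberrating Layers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for photoacoustic tomography when a thick, strongly
    aberrating layer (for example bone or a Perspex slab) lies between the
    optical absorbers and a linear ultrasound array.  Implements a
    Fresnel-Kirchhoff diffraction forward model for RF-signal synthesis with
    selectable obliquity factors, wave-based, delay-and-sum and straight-ray
    beamforming, a pulse-echo matched-filter estimator of the aberrator
    thickness profile, and a regularized ADAM joint inversion that recovers
    both the unknown aberrator profile and the initial pressure distribution
    from measured RF traces.  Includes synthetic phantom generators for
    reproducible numerical studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
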