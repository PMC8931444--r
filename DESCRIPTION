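Package: msotpipe
Title: Image Formation for Handheld Multispectral Optoacoustic Tomography
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Model-based image formation for handheld multispectral
    optoacoustic (photoacoustic) tomography with co-registered ultrasound.
    Implements a two-medium (coupling-cavity / tissue) refracted-travel-time
    acoustic forward model with total-impulse-response correction,
    Butterworth band-pass signal conditioning, non-negative
    Tikhonov-regularized reconstruction with L-curve parameter selection,
    two-level elastic motion correction with frame compounding, spectral
    median adjustment, constrained linear chromophore unmixing,
    optoacoustic/ultrasound affine co-registration, contrast-to-noise and
    line-profile resolution metrics, and the accompanying visualization
    transforms. A synthetic phantom simulator provides ground-truth data so
    the whole pipeline is testable without scanner hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    signal,
    pracma,
    yaml,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
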