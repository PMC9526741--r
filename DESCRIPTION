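Package: speckletrack
Title: Tracking Hidden Objects Through Scattering Media via Speckle
    Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward simulation and correlation-based tracking of objects
    hidden behind strongly scattering layers. Implements an incoherent
    forward model in which every point of a hidden scene contributes an
    independent speckle pattern on the detector, with pairwise speckle
    correlations governed by the optical memory effect, plus the
    correlation pipeline built on mean-subtracted FFT correlations:
    autocorrelation imaging, cross-correlation between frames, and the
    background-cancelling differential correlation whose paired
    positive/negative lobes localize and track moving hidden objects in
    real time and beyond the memory-effect field of view.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    tiff,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
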