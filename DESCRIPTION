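Package: simqc
Title: Quality Control for Structured Illumination Microscopy Data
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scriptable quality-control suite for three-dimensional
    structured illumination microscopy (3D-SIM). Provides raw-data checks
    (channel intensity profiles, raw Fourier projection, motion and
    illumination variation, modulation contrast-to-noise ratio with a
    suggested Wiener filter parameter), reconstructed-data checks
    (intensity histogram with min-to-max ratio, spherical aberration
    mismatch, lateral/orthogonal/radial Fourier plots, modulation contrast
    map), system-calibration tools (illumination pattern focus,
    illumination phase steps), image utilities (pseudo-widefield,
    threshold and 16-bit conversion, stack FFT, dimension reordering,
    multi-page TIFF I/O), a batch report runner, and a synthetic raw-SIM
    acquisition simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    png,
    jsonlite,
    signal,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
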