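Package: iolbench
Title: Field-Tracing Optical Bench Simulation for Intraocular Lenses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a model-eye optical bench for intraocular lenses
    (IOLs): a coherent scalar field from a USAF-1951 resolution target is
    propagated by the band-limited angular spectrum (spectrum of plane waves)
    method through an aspheric model cornea, a water-filled wet cell with
    glass windows, and a decentered or tilted spherical-aberration-correcting
    IOL to a retinal screen. Computes retinal images, point spread functions,
    Strehl ratios, modulation transfer functions and Zernike wavefront
    coefficients, and provides a geometric ray-tracing comparator
    (exit-pupil optical path difference to pupil-function PSF/MTF) to expose
    the divergence between wave-optical and ray-optical predictions under
    lens misalignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
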