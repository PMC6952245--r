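Package: vesselflow
Title: Blood-Flow Direction from Short Surgical Microscope Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the direction of blood flow in a segmented vessel from a
    few seconds of colour video acquired by a surgical microscope. The pipeline
    stabilises the clip with an affine registration, amplifies subtle pulsatile
    colour changes in the 0.8-3 Hz band (Eulerian colour magnification), traces
    an ordered centerline polyline from the vessel labelmap, extracts per-vertex
    green-channel photoplethysmographic signals, estimates the heart rate from
    the Fourier spectrum, and infers flow direction from reliable phase
    differences between adjacent vertices, with automatic arrow annotation. A
    synthetic pump-driven vessel phantom simulator provides ground-truth videos
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    EBImage,
    jsonlite,
    yaml,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
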