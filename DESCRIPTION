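Package: dffocm
Title: Dynamic Full-Field Optical Coherence Microscopy Reconstruction and
    Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processing chain for dynamic full-field optical coherence
    microscopy (d-FF-OCM). Reconstructs conventional FF-OCM amplitude images
    from four phase-stepped interferograms, computes per-pixel temporal
    fluctuation spectra from raw camera time-stacks and encodes three
    frequency bands as an RGB composite, estimates image resolution by
    Fourier ring correlation and contrast by contrast-to-noise ratio, and
    models the coherence-gate/confocal-gate co-registration needed when
    focusing through refractive-index-mismatched tissue. A synthetic
    Linnik-interferometer stack simulator with prescribed scatterer dynamics
    and shot-noise-limited detection provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
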