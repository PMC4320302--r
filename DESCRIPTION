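Package: msirp
Title: Random Projection Segmentation of Mass Spectrometry Imaging Data
Version: 0.1.0
Authors@R: person("msirp", "developers", role = c("aut", "cre"),
    email = "msirp@example.org")
Description: Streaming Gaussian random projection for mass spectrometry
    imaging (MSI). Reads and writes imzML, projects spectra one pixel at a
    time onto a seeded Gaussian basis (A = QX), selects the number of
    projections automatically from the decay of the normalized first
    singular value (exponential fit, analytic point of maximum curvature,
    two-thirds-of-maximum rule), segments pixels by k-means on the projected
    scores, recomputes per-cluster molecular profiles from the raw spectra,
    and quantifies segmentation reproducibility against repeated random
    bases and a PCA baseline. Includes a synthetic liver-like MSI phantom
    generator with ground-truth labels so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
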