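Package: nailsv
Title: Speckle-Variance OCT Analysis of Laser-Assisted Trans-Nail Drug Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies topical drug diffusion through fractional-laser
    microthermal ablation zones (MAZs) in the nail plate from time-series
    optical coherence tomography (OCT) B-scans. Implements reference-frame
    speckle variance with depth-cumulative shadow correction, nail-surface
    segmentation and axial realignment, MAZ depth/diameter morphometry, and
    region-of-interest diffusion time courses with onset/saturation times and
    speckle-variance center-of-mass trajectories. Ships a seeded dynamic-speckle
    phantom with known ground truth so every stage is verifiable without
    clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
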