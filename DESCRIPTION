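Package: nemaclear
Title: Topological Defect Analysis of Mesothelial Monolayers and Cancer
    Spheroid Clearance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies nematic order in confluent monolayers of elongated
    cells and relates half-integer topological defects to local cell
    velocity, cell density, and ovarian-cancer spheroid clearance.
    Estimates director fields from grayscale microscopy via the structure
    tensor, detects and tracks +1/2 and -1/2 defects by winding number,
    measures cell velocity with subset image correlation (PIV) and
    summarizes it in defect-centered frames, profiles nuclear-intensity
    cell density versus radius around defects, and fits normalized
    clearance rates of cancer spheroids classified by defect proximity.
    Ships a synthetic-scene generator with planted ground truth so every
    stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    jsonlite,
    nortest,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
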