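Package: flowcone
Title: Cone-Growth Image Analysis of Powder Flowability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Real-time cone-growth analysis of pharmaceutical powder
    flowability. Extracts flow curves from image stacks of a growing
    particle pile by vertical slicing and bright-area measurement, fits
    the geometric power-law growth model y = a + b*t^c whose ideal-cone
    exponent is 1/3, quantifies avalanche behaviour (count, amplitude,
    wavelength) on the detrended curve, measures static angle of repose
    and flow time from frames, and computes Crofton-perimeter sphericity
    for pellet/granule classification. Includes central-composite-design
    construction and response-surface regression with PRESS-based
    predicted R-squared, Pearson correlation matrices, a packaged
    24-run pellet/granule study dataset, and a simulator producing
    ground-truth pile stacks, flow curves, particle silhouettes and
    design responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    tiff,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
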