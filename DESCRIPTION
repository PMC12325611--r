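Package: dsbmotion
Title: Double-Strand-Break Mobility and Resection Analysis for Budding Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies the mobility of fluorescently labeled chromosomal
    loci (such as an HO-induced double-strand break marked by Ddc2-GFP)
    from two-channel 3D time-lapse microscopy. Implements fiducial-marker
    drift correction against the spindle-pole body, time-averaged
    mean-squared-displacement analysis, and a closed-form
    radius-of-confinement estimator, together with restriction-enzyme qPCR
    resection-fraction and HO-cutting calculators, clonogenic viability
    summaries, and many-to-one (Dunnett) group comparisons. A synthetic-data
    generator produces confined trajectories, rendered image stacks, qPCR Cq
    tables, and colony counts with known ground truth so every stage of the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    tiff,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    mvtnorm
Config/testthat/edition: 3
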