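Package: tensiomorph
Title: Tissue Surface Tensiometry and Gastrulation Morphometrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Measurement stack for characterizing tissue-scale forces during
    amphibian gastrulation. Implements axisymmetric drop shape analysis (ADSA)
    of tissue surface and interfacial tension under the Young-Laplace model,
    including forward integration of sessile drop profiles and simplex fitting
    of theoretical shapes to observed aggregate outlines; parallel-plate
    compression tensiometry; push-back (thickening-force) trace decomposition
    with onset detection; the interfacial-tension to convergence-force model
    F = sigma * L; and time-lapse morphometrics of tissue convergence,
    thickening, spherical-geometry-corrected areas, and blastopore closure.
    A synthetic-data module generates drop profiles, rendered drop images,
    force traces, and fiduciary-point track tables with known ground truth so
    every estimator is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    EBImage,
    mgcv,
    minpack.lm,
    pracma,
    stats,
    graphics,
    grDevices,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
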