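Package: shapeflow
Title: Shape-Driven Surrogate Modelling of Aortic Pressure and Velocity Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds statistical shape models of the thoracic aorta from
    control-point/momenta kernel deformations, samples synthetic cohorts in a
    truncated PCA score space, generates node-correspondent ground-truth
    pressure and velocity fields with a deterministic Poiseuille-based
    pseudo-CFD closure, trains dense ReLU surrogate networks with a frozen
    inverse-PCA reconstruction stage, and evaluates predictions with
    range-normalised absolute errors, Bland-Altman agreement, centerline
    gradient curves and the discrete Frechet distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    FNN,
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    truncnorm,
    optparse,
    withr
Config/testthat/edition: 3
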