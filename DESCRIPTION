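Package: dnpflow
Title: Divisive-Normalization Gain Control and Phase-Based Motion Detection
    for Fly-Inspired Vision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the early visual system of the fruit fly as a cascade of
    two divisive normalization processors (DNPs): an intensity/contrast
    gain-control front end emulating the photoreceptor/amacrine-cell layer
    (feedforward, local-feedback, pooled-feedback and adaptive-feedback
    variants, with closed-form steady states), and a phase-based elementary
    motion detector that extracts motion direction and speed from the Radon
    transform of the local-phase time derivative over a circular spatial
    frequency domain (the Phase Motion Indicator). Ships a synthetic-video
    generator (translating textures with ground-truth flow, brightness and
    contrast staircases, photoreceptor saturation, additive noise) and an
    angular-error / end-point-error evaluation protocol so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
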