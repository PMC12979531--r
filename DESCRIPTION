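Package: popspike
Title: Spike-Count Mixed Models and Population State-Space Analysis for
    Conspecific-Video Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing binned single-unit spike counts recorded
    while animals view naturalistic videos of conspecifics and matched
    control shapes. Provides a negative-binomial (NB2) random-intercept
    generalized linear mixed model engine based on the Laplace
    approximation, Wald and likelihood-ratio inference, estimated marginal
    means, Holm-adjusted contrasts and zero-inflation diagnostics; a
    per-unit selectivity classifier (actor-, behavior-,
    actor-and-behavior-selective, visually selective and sound-modulated
    units) with between-region proportion tests; population time-course
    models locating 200 ms bins that depart from baseline; pseudo-
    simultaneous population state-space trajectories from principal
    components with per-timepoint Euclidean divergences; low-level
    stimulus equalization (region-wise luminance matching and
    orientation-preserving spatial-frequency matching in HSV space); and a
    synthetic-data generator with planted ground truth covering the full
    stimulus set, pseudorandomized session schedules and negative-binomial
    spike counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    tools
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    MASS,
    knitr,
    rmarkdown
Config/testthat/edition: 3
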