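Package: screwscape
Title: Surrogate-Model Exploration of Locking-Plate Screw Orientations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring how the orientations of the seven proximal
    screws of a proximal-humerus locking plate affect peri-screw bone strain,
    using neural-network surrogates of a finite-element response surface.
    Provides a parametric capsule model of the screws with exact
    screw-screw collision detection and tip-to-joint-distance length
    solving; a synthetic strain oracle with calcar-screw dominance standing
    in for the finite-element solver; Latin Hypercube and full-factorial
    designs over discrete angle grids; small multilayer perceptrons trained
    from scratch with Levenberg-Marquardt and Bayesian-regularization
    backpropagation; and the evaluation statistics of the study design
    (classification accuracy, regression metrics, Welch tests, per-screw
    strain-variation heatmaps, strain-range comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
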