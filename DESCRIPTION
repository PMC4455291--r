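Package: glomenose
Title: Olfactory-Bulb-Inspired Adaptive Pre-Processing for Electronic Noses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates drifting metal-oxide gas-sensor arrays and implements an
    adaptive multi-compartment glomerular network (mitral-cell branch potentials
    under multiplicative periglomerular feed-forward inhibition, with nonlinear
    local Hebbian weight adaptation) as a pre-processor that stabilises odor
    classification against correlated sensor drift, jumps, and sensor faults.
    Includes a from-scratch PLS-DA classifier, experiment drivers comparing the
    network pipeline against direct and class-averaged PLS-DA baselines, a
    16-sensor fault sweep, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    knitr,
    rmarkdown
Config/testthat/edition: 3
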