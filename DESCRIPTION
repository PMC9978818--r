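Package: paart
Title: Avidity Binning of Polyclonal Antibody Dissociation Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resolves heterogeneity in the avidity of polyclonal antibodies
    from label-free biosensor (biolayer interferometry or surface plasmon
    resonance) dissociation time-courses. Dissociation phases are fit to
    sums of exponentials of increasing order and the parsimonious number of
    antibody components is selected by the Akaike information criterion,
    yielding per-component dissociation rate constants, their standard
    errors and their fractional contributions to the bound response. Also
    provides the 1:1 Langmuir model, a heterogeneous-analyte (competing
    reactions) mass-action model with forward simulation and global
    fitting, and a synthetic sensorgram generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
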