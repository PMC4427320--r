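Package: luxrfit
Title: Equilibrium Modeling and Ensemble Fitting of Two-Signal LuxR
    Dose-Response Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward equilibrium model of LuxR transcriptional activation by
    two competing acyl-homoserine lactone signals (C8-HSL and 3OC6-HSL), with
    cooperative complex formation, a total-LuxR conservation constraint and
    competitive lux-box occupancy.  Provides the full inference pipeline used
    to estimate the six interaction parameters from well-plate luminescence
    grids: an embedded linear scale fit on square-root luminescence, a
    log-scale least-squares loss, a global random seed search followed by
    Nelder-Mead refinement, and ensemble summaries (medians and percentile
    ranges) over many fits to replicate plates.  Includes a synthetic
    well-plate generator with multiplicative lognormal noise for
    parameter-recovery studies, plate CSV readers and writers, conversion of
    scaled dissociation constants to absolute nanomolar constants, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
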