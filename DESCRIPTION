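Package: nasaldosim
Title: Formaldehyde DNA-Adduct Dosimetry in the Rat Nasal Mucosa
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tissue dosimetry model for endogenous and exogenous formaldehyde
    in the F344 rat nasal mucosa. A nine-state nonlinear ODE system couples
    CFD-derived wall flux of inhaled formaldehyde with endogenous production,
    glutathione conjugation, saturable enzymatic oxidation of the
    formaldehyde-glutathione complex, and formation and repair of
    deoxyguanosine (DG) monoadducts and DNA-protein crosslinks (DPX). The
    package ships the compiled rat nasal adduct dataset, the inhalation
    exposure protocols under which it was collected, units conversions between
    adducts-per-deoxyguanosine and tissue concentration, bounded Nelder-Mead
    calibration with a relative least-squares cost, synthetic-data generation
    for parameter recovery, and dose-response analyses (endogenous/exogenous
    crossover concentrations, DPX:DG ratios, multi-week time courses).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    withr
Config/testthat/edition: 3
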