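Package: petkin
Title: Compartmental Kinetic Modeling and Occupancy Analysis for Dynamic Brain PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for dynamic brain PET studies with
    arterial blood sampling: metabolite-corrected arterial input functions
    (Hill-type parent-fraction models, ultrafiltration plasma free fraction),
    one- and two-tissue compartment model fitting with AIC model selection
    and relative standard errors, scan-truncation stability analysis for
    detecting radio-metabolite contamination, Lassen occupancy plots on V_T
    or V_T/f_P with nondisplaceable volume and binding potential derivation,
    and Guo cross-tracer plots. Includes a seeded synthetic-study generator
    that emulates baseline and blocking scans of fast-metabolizing GSK-3
    radiotracers in non-human primates, including a brain-penetrant
    radio-metabolite and plasma free-fraction shifts under blocking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
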