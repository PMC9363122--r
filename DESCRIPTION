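Package: osteosim
Title: Simulation and Optimization of Pharmacological Osteoporosis Therapies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mechanistic simulator of bone remodeling and its pharmacological
    modulation in postmenopausal osteoporosis. An ordinary-differential-equation
    core describes a representative bone remodeling unit (osteoclast and
    osteoblast lineages, osteocytes, sclerostin, bone density and mineral
    content) driven by an age-dependent estrogen input; drug modules add
    pharmacokinetics and pharmacodynamics for RANKL antibodies (denosumab),
    sclerostin antibodies (romosozumab, blosozumab), bisphosphonates
    (alendronate) and PTH analogs (teriparatide). The package builds hybrid
    aging/treatment datasets from digitised clinical series, calibrates free
    model parameters by bounded multi-start least squares, generates synthetic
    clinical-style fixtures for parameter-recovery studies, and enumerates and
    ranks sequential combination-therapy regimens by short- and long-term bone
    mineral density outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
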