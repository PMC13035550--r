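Package: ratheart
Title: Multiscale Cardiopulmonary Modeling of Postnatal Hyperoxia in Pediatric Rats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Subject-specific, multiscale model of the pediatric rat heart and
    circulation for studying postnatal hyperoxia, a rodent model of human
    preterm birth. Couples a five-state crossbridge moment model with
    metabolite-dependent transition rates to biventricular spherical-cap
    (TriSeg-type) mechanics and a closed-loop six-compartment lumped
    circulation. Provides local sensitivity analysis with Fisher-information
    subset selection, multistart pressure-volume loop calibration,
    catheter-data preprocessing, derived physiologic metrics (mean pulmonary
    arterial pressure, septal bounce, myofiber power intensity, stroke work),
    group statistics with linear discriminant separability, and a seeded
    synthetic-cohort generator that emulates sequential conductance-catheter
    recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
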