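Package: cardiomef
Title: Closed-Loop 0D Cardiac Electromechanics with Mechanoelectric Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, closed-loop model of biventricular cardiac
    electromechanics built around the mechanoelectric feedback (MEF)
    mechanisms: stretch-activated channels added to a human ventricular
    myocyte ionic model, a cross-bridge active-tension model with length
    and shortening-velocity dependence, an orthotropic passive myocardial
    material reduced to the fiber axis, a multi-patch thin-wall ventricle
    surrogate, and a lumped closed-loop circulation. Ships reproducible
    experiment pipelines (MEF ablation, stretch-trigger sweeps, left
    bundle branch block and cardiac resynchronization pacing) together
    with pressure-volume loop and per-patch stretch/tension metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    generics,
    ggplot2,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    knitr
Config/testthat/edition: 3
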