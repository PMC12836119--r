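Package: nemaload
Title: Genetic Load Estimation from Serial Sib-Mating Line-Extinction Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analyzing serial full-sib-mating line-extinction
    experiments in obligately outcrossing nematodes. Computes inbreeding
    coefficients under repeated sib mating, fits a logistic model of cross
    success on the inbreeding coefficient F, converts the coefficients to
    Morton-style expressed (A_R) and concealed (B_R) genetic load on the
    reproducing-pair scale, decomposes failure by life-cycle stage
    (copulation, fertility, development), estimates relative fitness of
    inbred lines from age-structured reproductive schedules via the
    Lotka-Euler equation, and simulates whole experiments for power and
    calibration studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
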