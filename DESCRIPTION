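Package: rodcascade
Title: Bottom-Up Kinetic Modeling of Vertebrate Rod Phototransduction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic mass-action simulation of the vertebrate rod
    phototransduction cascade, with an emphasis on the recovery phase of the
    photoresponse. Implements phosphorylation-state-indexed rhodopsin shutdown
    with linear rhodopsin-kinase and arrestin affinity schedules, an explicit
    calcium/recoverin feedback on rhodopsin kinase, a dynamic arrestin
    monomer-dimer-tetramer storage equilibrium, RGS-mediated effector shutdown,
    and a cGMP/calcium back end driving a normalized photocurrent observable.
    Provides an in-silico mutant engine (fold-expression scaling with dark-state
    re-equilibration), flash/step stimulus protocols, and standardized
    photoresponse descriptors (saturation time, recovery time constant, and the
    Pepperberg dominant time constant), together with SBML export and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
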