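Package: ectcord
Title: Tumor-Cord Drug Transport and Boolean Mechanism Inference for
    Electrochemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates drug transport in an axisymmetric tumor cord during
    electrochemotherapy: electric-field-dependent membrane and vessel-wall
    permeabilization through a sigmoidal conductivity model, vessel
    vasoconstriction and recovery with the induced tissue velocity field,
    porous-tube leakage flow and intravascular advection, tri-exponential
    or uniform inlet pharmacokinetics, and the coupled
    extracellular/intracellular/bound species equations solved implicitly
    on a moving annular grid.  A propositional (Boolean) inference engine
    converts the spatio-temporal trends of the concentration ratios
    C2/C1, C3/C1 and C3/C2 into maps of dominant reaction and transport
    mechanisms (internalization, externalization, association,
    dissociation, extracellular transport), with every conclusion certified
    by exhaustive truth-table enumeration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
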