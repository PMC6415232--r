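Package: ccgel
Title: Counterion Condensation and Collapse Transitions in a One-Dimensional
    Polyelectrolyte Gel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Equilibrium theory of a one-dimensional polyelectrolyte gel: a
    line of charged beads joined by zero-rest-length Hooke springs, screened
    by dissolved salt. Implements the closed-form per-bead free energies of
    the Debye-Hueckel (low charge density) and counterion-condensation (high
    charge density) branches, solvers for the equilibrium bead spacing on
    each branch, piecewise free-energy landscapes with bistability detection,
    bisection mapping of the Bjerrum-length interval in which stretched and
    contracted states coexist, and a condensed-counterion spring-stiffening
    model of cooperative collapse. Includes a command-line interface and
    parameter presets for standard sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
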