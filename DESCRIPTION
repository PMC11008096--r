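Package: cphmdr
Title: Continuous Constant-pH Lambda-Dynamics for Polarizable Multipole Force Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A continuous constant-pH molecular dynamics (CpHMD) engine for
    polarizable atomic-multipole potentials. Titration and tautomer states
    evolve as extended lambda-dynamics variables alongside Cartesian
    coordinates. Provides analytic state-variable derivatives of the buffered
    14-7 van der Waals, permanent-multipole Ewald/PME, and induced-dipole
    polarization energies requiring a single self-consistent field per step,
    plus pH replica exchange, Bennett-acceptance-ratio model-compound
    parameterization, and Hill-equation pKa estimation. Includes deterministic
    generators for small periodic test systems (water boxes, ionic lattices,
    titratable model compounds) and a finite-difference gradient checker.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
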