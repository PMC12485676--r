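Package: mtctt
Title: Microtubule Lattice Models and Alpha-Tubulin C-Terminal Tail
    Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction of 13-protofilament, 3-start microtubule lattice
    models from a single alpha/beta-tubulin dimer, addition of disordered
    C-terminal tails with author residue numbering, detection of tail-body
    salt bridges in coordinate trajectories (with axial periodic boundary
    support), assignment of contacts to named interaction sites on the
    tubulin body, and computation of per-glutamate interaction-rate
    matrices and tail-inaccessibility traces.  A synthetic trajectory
    generator plants two-state Markov binding kinetics with known
    stationary occupancies so that every analysis stage can be validated
    against ground truth without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
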