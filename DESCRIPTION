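Package: torsionbo
Title: Bayesian-Optimization Conformer Search over Torsion Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Active-learning search for low-energy molecular conformers.
    A Gaussian-process surrogate with a periodic kernel models the potential
    energy surface as a function of dihedral angles; an exploratory
    lower-confidence-bound acquisition function selects the next
    single-point energy evaluation. Post-processing extracts all local
    minima of the learned surface by multi-start L-BFGS minimization and
    purges duplicates. Candidate conformers are refined by geometry
    relaxation, harmonic vibrational free-energy corrections from a
    finite-difference Hessian, and optional high-level single-point energy
    deltas, yielding a staged conformer energy hierarchy. Energy backends
    are pluggable behind a calculator interface; an analytic torsional
    potential generator, a simple molecular-mechanics force field and a
    file-exchange bridge to external codes are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
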