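Package: molsym
Title: Continuous Symmetry and Chirality Measures for Molecular Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how far a molecular structure deviates from a chosen
    point-group symmetry via the continuous symmetry measure (CSM) and from
    achirality via the continuous chirality measure (CCM). Reads XYZ, SDF
    (V2000) and PDB files, infers covalent bonds, and computes atom
    equivalence classes by neighbourhood colour refinement. Provides an exact
    engine that enumerates structure-preserving permutations under cycle
    constraints, plus approximate engines for large structures: greedy and
    Hungarian assignment on the symmetry-operation distance matrix,
    permutation-direction iterations, Fibonacci-lattice multistart over axis
    directions, and a prioritized branch-and-bound over structure-preserving
    permutations. Also computes upper/lower CSM bounds, the nearest symmetric
    structure, and bond-preservation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ChemmineR,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
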