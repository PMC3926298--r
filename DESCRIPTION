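Package: nnsymmetry
Title: Tests of Spatial Symmetry in Nearest-Neighbor Structure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tests of spatial symmetry in the mixed and shared
    nearest-neighbor (NN) structure of multi-class planar point patterns.
    Implements Pielou's first (McNemar/Bowker and exact binomial) and second
    (Q-symmetry contingency table) symmetry tests, Dixon's symmetry test with
    exact random-labeling moments and its multi-class quadratic-form
    extension, variants of Fisher's exact test on the Q-symmetry table
    (table-inclusive, table-exclusive, mid-p, twice-table-inclusive, and
    Tocher-randomized), Monte Carlo randomization tests, restricted and
    unrestricted pairwise and one-versus-rest post hoc tests, closed-form
    local power and Pitman asymptotic efficiency utilities, and point-pattern
    generators (CSR, random labeling over uniform and Matern-cluster
    backgrounds, and six alternative pattern families) with a Monte Carlo
    harness for empirical size and power studies. Nearest-neighbor relations
    may be computed from planar coordinates or from a user-supplied
    dissimilarity matrix.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
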