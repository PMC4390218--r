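Package: biteFEM
Title: Finite-Element Bite Modeling for Skull Biomechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative skull biomechanics using linear-elastic
    finite-element analysis on tetrahedral meshes. Converts jaw-adductor
    muscle definitions (insertion patches, contraction pressures, gape
    angles) into distributed surface tractions, solves the static elasticity
    problem under prehension, jaw-joint and occipital constraints, recovers
    Von Mises stress fields, and extracts bite forces as constraint
    reactions. Includes quasi-homothetic scaling laws (volume two-thirds
    power and enclosing-surface methods) for cross-specimen comparison,
    deterministic generators of skull-like verification fixtures, and
    readers and writers for Gmsh, VTK and Abaqus tetrahedral mesh formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
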