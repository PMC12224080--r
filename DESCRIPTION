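Package: xtalbench
Title: Structure-Specific Restraint Benchmarking for Small-Molecule Crystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for scoring theoretically optimized molecular geometries
    against accurate single-crystal X-ray diffraction data. Builds
    molecule-in-cluster systems from a crystal structure by space-group
    symmetry expansion, derives tight bond (DFIX) and angle-as-distance
    (DANG) restraints from any set of optimized coordinates, runs restrained
    and unrestrained independent-atom-model least-squares refinement against
    Bragg intensities, and quantifies theory-versus-experiment agreement by
    the Delta-R1(F) penalty and root mean square Cartesian displacement
    (RMSCD). Includes TLS rigid-body thermal-motion analysis with
    libration-corrected bond lengths, readers and writers for a CIF subset,
    SHELX HKLF-4 reflection files and SHELXL-dialect restraint files, and a
    deterministic synthetic-fixture generator so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
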