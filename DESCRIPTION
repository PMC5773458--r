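Package: aromprofile
Title: Structure-Based 3D-QSAR Profiling of Aromatase Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric detection of protein-ligand interaction features with
    piecewise-linear block functions, steric-clash based selection of bioactive
    docking poses, integration of hydrophobicity density over the ligand
    contact surface (log PC), an electronic heme-coordination descriptor built
    on condensed Fukui functions, and a weighted multiple linear regression
    QSAR with genetic-algorithm feature selection.  Includes a synthetic
    binding-site and cohort generator so the whole pipeline can be exercised
    and validated without external structure downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    bio3d,
    ChemmineR,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
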