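Package: fieldqsar
Title: Grid-Field 3D QSAR, Pharmacophore Modelling and Ligand-Based Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ligand-based discovery workflow for congeneric small-molecule
    series: template alignment of 3D structures, Gasteiger-Marsili (PEOE)
    partial charges, CoMFA-style steric/electrostatic/hydrophobic
    probe-interaction fields on a rectangular grid, stepwise-forward
    descriptor selection with partial least squares regression, full
    statistical validation (leave-one-out q2, external pred_r2, F-test,
    Y-randomization Z-scores), rule-based pharmacophore perception with
    common-hypothesis enumeration and survival scoring, and library
    screening with activity prediction. Includes a synthetic
    congeneric-series generator with planted linear structure so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on PATH
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
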