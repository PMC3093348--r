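Package: sarpose
Title: SAR-Guided Evaluation of Docking Pose Ensembles by Common-Scaffold
    Clustering and Interaction Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for structure-activity-guided evaluation of multi-ligand
    docking pose ensembles, developed around the P-glycoprotein inhibitor
    use case. Poses of a ligand series sharing a common scaffold are
    compared by in-place scaffold RMSD, clustered by complete linkage, and
    filtered to common-scaffold clusters spanning most of the series.
    Per-residue protein-ligand interaction fingerprints (contacts, geometric
    hydrogen bonds, aromatic interactions), steric-clash counts, side-chain
    rotamer scans and ligand-efficiency metrics (LLE, LE, FQ) support
    prioritisation of binding hypotheses. A deterministic synthetic scene
    generator produces toy receptors and pose ensembles with planted
    cluster structure, hydrogen bonds and clashes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
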