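Package: aggfold
Title: Self-Association and Aggregation-Driven Folding Analysis for
    Multi-Chain Peptide Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying peptide self-association and
    aggregation-driven folding in multi-chain trajectories. Provides a
    kinematic trajectory generator with scripted aggregation and
    helix-straightening events, multi-model PDB input/output, rigid-body
    superposition and fluctuation analysis, Shrake-Rupley solvent-accessible
    surface area decomposed by residue class, dihedral-based helix-state
    classification with windowed occupancy, GROMOS conformational clustering,
    Cartesian backbone principal component analysis, periodic contact-graph
    aggregate detection, per-residue intermolecular contact statistics, and
    sigmoid folding-kinetics fitting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
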