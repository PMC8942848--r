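Package: gpcrdimer
Title: Conformational-State, Dimer-Interface and Allosteric-Network Analysis for GPCR Homodimers
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative structural comparison of G-protein-coupled receptor
    (GPCR) conformational states, with tooling developed around the fungal
    pheromone receptor Ste2 homodimer. Reads PDB/mmCIF coordinate files and
    multi-model PDB/DCD/XTC trajectories; performs Kabsch superposition,
    per-residue C-alpha displacement, helix-axis kink and axial-rotation
    measurements; characterises the dimer interface (Shrake-Rupley solvent
    accessible surface area, buried interface area, typed residue contacts,
    contact persistence over trajectories, and a reduced-forcefield
    inter-protomer interaction energy); estimates orthosteric-pocket volumes by
    grid flood fill; and computes torsion-angle mutual-information networks
    with highest-information shortest "pipelines" between ligand-binding and
    G-protein-coupling sites, ranked by strength, plus per-residue hubscores.
    A seeded synthetic-data generator (ideal helical dimers with planted
    rigid-body motions, von Mises coupled-torsion trajectories, planted
    contact time series) makes every stage verifiable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
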