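Package: allocross
Title: Trajectory Analysis of Interdomain Allosteric Crosstalk in Two-Domain Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular dynamics trajectories of two-domain
    allosteric proteins such as the Hsp70/DnaK chaperone, in which a nucleotide
    binding domain (NBD) and a substrate binding domain (SBD) communicate
    through a flexible interdomain linker. Implements gromos conformational
    clustering on residue subsets with decomposition of cluster populations by
    ligand state, distance-fluctuation (coordination) maps, centre-of-mass
    cloud statistics of the mobile domain after superposition on the anchor
    domain, persistent contact and hydrogen-bond tables, interface maps from
    time-averaged minimum distances, beta-strand content, and hinge dihedral
    statistics. A synthetic trajectory generator produces two-domain hinge
    ensembles with programmable state mixtures, planted interactions and
    planted secondary structure, providing exact ground truth for every
    analysis stage. Reads PDB and multi-model PDB structures and DCD
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
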