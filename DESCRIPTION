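Package: glowives
Title: Clash-Tolerant Ligand Pose Sampling with Softened van der Waals
    Potentials and Pocket-Minimized Receptor Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ligand pose-sampling protocols for cross-docking, where the
    docking receptor's pocket may clash with the correct ligand pose. GLOW
    pools poses generated under a normal and a softened (clash-capped) van
    der Waals potential; IVES turns top-scored seed poses into an ensemble
    of pocket-minimized receptor conformations (residues within a shell of
    the seed pose relax, the rest stay fixed) and redocks against every
    member with both potentials. Includes a compact Monte-Carlo docking
    engine, symmetry-corrected RMSD evaluation against a reference pose,
    and a synthetic cross-docking benchmark generator, so the full pipeline
    runs and is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
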