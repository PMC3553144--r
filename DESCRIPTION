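Package: ankevol
Title: Evolutionary and Structural Analysis of Ankyrin-Repeat Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A multi-stage pipeline for the comparative analysis of
    ankyrin-repeat protein families such as the IkB inhibitors of NF-kB.
    Provides global pairwise similarity tables and homolog filtering, PEST
    motif detection, Jukes-Cantor protein distances with neighbor-joining
    trees and nonparametric bootstrap, Gu-style type I and type II
    functional-divergence estimation between subfamily clades, site-wise
    Ka/Ks by Nei-Gojobori counting, anisotropic network model (ANM) normal
    modes with B-factor comparison, and structural-ensemble principal
    component analysis with ANM/PCA mode overlap. Synthetic-data generators
    with known ground truth (sequence families evolved on known trees,
    codon alignments with per-site omega, ankyrin-like C-alpha chains and
    conformer ensembles with planted deformation directions) make every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
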