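Package: LigandRMSD
Title: Binding-Site Alignment Scoring by Ligand Superposition and Drug
    Promiscuity Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores protein binding-site structural alignments by the quality
    of the induced ligand superposition (LigandRMSD): the ligand-ligand RMSD
    under the alignment's rigid transform minus the optimal rigid-superposition
    RMSD of the same ligand pair under the same atom correspondence. Provides
    PDB-format ligand extraction with blacklist filtering, element-labelled
    molecular graphs with isomorphism and maximum-common-subgraph atom mapping,
    Kabsch superposition, bound-conformer average-linkage clustering, global
    sequence alignment with 95 percent identity target clustering, the
    drug-promiscuity statistics linking target counts to physicochemical and
    structural properties, seeded synthetic-fixture generators, and a
    three-stage analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    ape,
    Biostrings,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
biocViews: StructuralBioinformatics, Cheminformatics, Clustering, Alignment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
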