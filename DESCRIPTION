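Package: AbAgRescore
Title: Rescoring of Antibody-Antigen Docking Decoys with Structure-Conditioned
    Confidence Metrics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reranking rigid-body antibody-antigen docking models
    using composite confidence scores derived from structure-conditioned
    AlphaFold2 inference. Provides poly-alanine template preparation for a
    merged single-chain query (artificial linker or residue-index gap
    strategies), CAPRI-style model quality evaluation (fraction of native
    contacts, interface RMSD, ligand RMSD and quality classification), the
    AF2 composite z-score rescoring function with docking-score orientation
    conventions, per-system ROC/enrichment/precision analytics, and a
    deterministic synthetic decoy generator so that the entire pipeline is
    exercisable without docking binaries or neural-network inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
biocViews: StructuralBioinformatics, Proteomics, Classification
RoxygenNote: 7.3.3
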