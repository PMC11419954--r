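Package: neoasurf
Title: Surface and Structural Foreignness Modelling of Peptide-HLA Class I Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling peptide-HLA class I (pHLA-I) complexes and for
    scoring the foreignness of mutant peptides against their wild-type
    counterparts. Provides a pHLA-I structure data model with PDB input/output,
    HLA groove trimming and peptide padding; structural comparison metrics
    (Kabsch superposition, TM-score, lDDT, pLDDT filtering, AUROC/AUPRC);
    molecular-surface meshing with per-vertex shape index, distance-dependent
    curvature and chemical features decomposed into geodesic polar patches;
    groove-plane geometry with outer-surface (TCR-exposed) selection; a
    miniature trainable peptide-conformation model with frame-aligned point
    error, distogram, torsion and violation losses including intermolecular
    peptide-HLA terms; and a wild-type/mutant foreignness scorer combining
    surface, spatial-structure and atom-group comparison blocks. Deterministic
    synthetic-fixture generators (idealized grooves, arch-conformation
    peptides, labelled pair corpora) support fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
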