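Package: quadbind
Title: Quadrupolar and Structure-Binding Strength Indices for Ligand Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for comparing how a nucleoside-analogue ligand binds in
    the crystalline solid state versus inside a protein-ligand complex.
    Implements 14N nuclear quadrupole resonance (NQR) parameter algebra
    (transition frequencies, quadrupole coupling constant, asymmetry
    parameter, electric field gradient tensors), combinatorial assignment of
    multi-line NQR spectra to nitrogen sites, six quadrupolar indices
    quantifying solid-state and complexation effects, seven structure-binding
    strength indices (SBSI) over docking energy decompositions and molecular
    similarity (fingerprint Tanimoto, atom-pair Tanimoto, maximum common
    substructure), Hirshfeld contact-surface enrichment statistics, and
    binding-mode / normalized B-factor comparison metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    ChemmineR,
    ChemmineOB,
    bio3d
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
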