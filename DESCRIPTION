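Package: binderprep
Title: Interface Curation and Design Filtering for Phosphopeptide Binder Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Annotates binder-target protein complexes for generative
    binder-design pipelines: interface hotspot and anti-hotspot detection
    from C-beta contacts and solvent accessibility, continuous super-hotspot
    weights from cross-chain neighbor density, side-chain-neighbor (SCN)
    packing metrics with folding-quality gates, disordered-terminus trimming
    and radial cropping of training examples, assembly of per-token 1D
    conditioning feature tensors, and geometric accept/reject filters for
    designed phosphotyrosine-binding proteins (phosphate hydrogen-bond
    counts, phosphotyrosine RMSD after binder superposition, and
    structure-prediction confidence gates). A deterministic synthetic-fixture
    generator builds idealized binder-phosphopeptide complexes so the whole
    pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
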