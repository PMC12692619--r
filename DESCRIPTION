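Package: bcepitope
Title: Linear B-Cell Epitope Profiling, Multi-Tool Consensus Calling and
    Structural Mapping for Allergen Sequences
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts linear B-cell epitopes in protein sequences by
    combining classical propensity-scale profiles (Hopp-Woods and
    Kyte-Doolittle hydropathy, Parker hydrophilicity, Emini surface
    probability, Karplus-Schulz flexibility, Jameson-Wolf antigenic
    index), Chou-Fasman and GOR-style secondary-structure prediction, and
    a two-state hidden Markov scorer with hydrophilicity mixing. Candidate
    regions from independent predictors are merged by a k-of-n
    residue-overlap consensus with minimum-length filtering, and consensus
    epitopes can be mapped onto predicted 3D structure models to report
    solvent exposure and per-residue model confidence (pLDDT). Ships
    transcriptions of published per-tool epitope tables for the seven
    sesame (Sesamum indicum) allergens as worked fixtures, and
    deterministic synthetic-data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    bio3d,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
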