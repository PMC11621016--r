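Package: xlms
Title: Cross-Link Search and FDR Benchmarking for MS-Cleavable
    Cross-Linking Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A search engine and benchmarking toolkit for cross-linking
    mass spectrometry (XL-MS) with MS-cleavable reagents such as DSSO.
    Identifies cross-linked peptide pairs from MS2 spectra by detecting
    cleavable-linker signature doublets, resolving candidate peptide
    pairs through a mass-indexed digest database, scoring matches with a
    set of spectral quality metrics and a trainable discriminant, and
    controlling the false discovery rate separately at the levels of
    cross-link spectrum matches, unique residue pairs and protein-protein
    interactions.  Includes a pairwise-mixing-scheme ground-truth model
    for empirical FDR benchmarking, an entrapment-database builder, a
    Zipf/Poisson simulator of false residue-to-residue links, a synthetic
    cross-linked-spectra generator with planted answers, and utilities
    for mapping identified residue pairs onto predicted protein
    structures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    nnet,
    bio3d,
    jsonlite,
    optparse,
    mzR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
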