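Package: motudelim
Title: Molecular Species Delimitation for COI Barcode Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for delimiting molecular operational taxonomic
    units (MOTUs) from aligned mitochondrial COI barcode alignments and
    specimen metadata. Computes pairwise genetic distances (p, JC69,
    Kimura 2-parameter) with pairwise deletion, summarises divergence by
    taxonomic rank, clusters sequences into MOTUs by furthest-neighbor
    (complete-linkage) threshold clustering with threshold sweeps and
    plateau detection, re-implements Automatic Barcode Gap Discovery
    (ABGD) recursive partitioning, performs Poisson Tree Processes (PTP)
    maximum-likelihood species delimitation on a rooted tree, and
    reconciles MOTU partitions against morphospecies labels to flag
    cryptic species, oversplit taxa, barcode-sharing taxa, and the
    integrative-taxonomy zone. Includes a Kimura-model sequence
    simulator for generating barcode libraries with controlled intra-
    and interspecific divergence structure.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
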