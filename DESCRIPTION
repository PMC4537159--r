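Package: BarcodeDelim
Title: Threshold-Based Species Delimitation from Single-Locus Barcode
    Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delimits candidate species from an aligned single-locus DNA
    barcode matrix (e.g. mitochondrial 16S rRNA) and nominal species
    labels. Computes uncorrected p-distances with pairwise deletion of
    ambiguous sites, clusters specimens into molecular operational
    taxonomic units (MOTUs) by single-linkage threshold clustering,
    diagnoses monophyly, paraphyly and polyphyly of nominal species on a
    supplied rooted tree, classifies flagged lineages as confirmed or
    unconfirmed candidate species or deep conspecific lineages using
    morphological concordance, and reports species-richness increase
    statistics. A Jukes-Cantor simulator generates barcode-like data sets
    with known species structure (cryptic lineages, missing data) so the
    whole pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    ape,
    phangorn,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
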