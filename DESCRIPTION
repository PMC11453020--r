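Package: pavkit
Title: Gene Presence/Absence Variation Analysis for Map-to-Pan Genomes
Version: 0.1.0
Author: Package Author
Maintainer: Package Author <author@example.org>
Description: Tools for pan-genome gene presence/absence variation (PAV)
    analysis from per-base read-depth tracks: coverage-breadth gene-loss
    calling over the exons of each gene's longest transcript,
    core/softcore/shell/cloud classification of the pan-genome,
    rarefaction-based modelling of pan-genome openness, Fisher-exact
    scans for presence-frequency selection between populations, and
    curation filters for nonreference contigs in map-to-pan assemblies.
    Includes a synthetic-data generator with known ground truth so every
    stage is testable without resequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    IRanges,
    Biostrings,
    minpack.lm,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
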