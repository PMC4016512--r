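Package: clemine
Title: Mining CLE and CLEL Peptide-Ligand Genes from EST and Genome Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering genes encoding secreted
    CLE and CLE-LIKE (CLEL) peptide ligands in plant EST and genomic
    sequence collections. Provides translated six-frame motif scanning with
    Smith-Waterman local alignment, species-aware greedy contig assembly of
    motif-positive ESTs with variant classification, a signal-peptide
    prediction gate for full-length precursor validation, gene-model
    construction by spliced EST-to-genome alignment including detection of
    alternative 3'-terminal acceptor exons, a mature-peptide catalog with
    cross-species deduplication and comparison to a reference peptide set,
    and Poisson-corrected Neighbour-Joining phylogenetics with bootstrap
    support. A synthetic-data generator plants genes with a known
    ground-truth manifest so the whole pipeline can be exercised and scored
    end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
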