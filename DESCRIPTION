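Package: pairsuite
Title: Contact Pair Extraction and Quality Control for Chromosome
    Conformation Capture Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts name-grouped local alignments of chimeric Hi-C and
    related chromosome-conformation-capture (3C+) sequencing reads into
    deduplicated, quality-controlled lists of genomic contact pairs in the
    4DN '.pairs' text format.  Provides parsing of chimeric alignments with
    configurable multi-ligation ("walk") policies and rescue of
    split-fragment pairs, canonical flipping and genomic sorting, removal
    of PCR duplicates by fixed-radius neighbour search with library
    complexity estimation, summary statistics including strand-oriented
    contact-frequency scaling P(s) and the orientation convergence
    distance, restriction-fragment annotation and ligation by-product
    classification, haplotype phasing of contacts, single-cell coverage
    filtering, predicate-based selection and random subsampling, and a
    synthetic 3C+ library simulator with full ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    yaml,
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
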