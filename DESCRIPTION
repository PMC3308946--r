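Package: edcas
Title: Amplicon-Based Quantification of A-to-I RNA Editing in the
    Serotonin 2C Receptor Editing Cassette
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying adenosine-to-inosine (A-to-I) RNA
    editing of the serotonin 2C receptor (5-HT2C) editing cassette from
    barcoded amplicon sequencing reads.  The package models the five
    editable adenosines (sites A, B, E, C and D), enumerates the 32
    possible mRNA editing isoforms and their 24 predicted protein
    variants, demultiplexes pooled reads by group barcode, applies an
    average/end error-probability quality filter, calls the base at each
    editing site by alignment to the unedited cassette reference, and
    aggregates calls into isoform count tables and per-site editing
    frequencies compared between groups with Fisher's exact test and
    Bonferroni correction.  Two orthogonal assays are included: a Sanger
    chromatogram peak-height editing-frequency estimator with
    site-specific calibration, and 2^-deltaCt relative-expression fold
    changes from qPCR cycle thresholds.  A synthetic-data module
    generates barcoded amplicon reads, chromatogram traces and qPCR
    records with known ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
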