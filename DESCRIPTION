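Package: clonefate
Title: Clonal Fate Analysis of Lentiviral Lineage Barcodes in Directed
    Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for clonal lineage-barcode analysis of directed
    differentiation experiments profiled by single-cell RNA sequencing.
    Recovers WSN-patterned lentiviral barcodes from amplicon reads (both
    10X side-reaction and genomic-DNA modes), merges sequencing variants
    by Levenshtein distance on barcode prefixes, assigns barcodes to cells
    with UMI-count and dominance filters, derives clone-level cluster
    probability distributions, tests clonal fate homogeneity with
    Jensen-Shannon-distance resampling against a matched-size null,
    compares clonal fate across split (parallel "identical twin")
    differentiations, and simulates binomial splitting with a calibrated
    loss coefficient to test whether barcode survival across splits is
    random or clone-heritable. Includes a synthetic-data generator that
    emulates barcoded-clone structure so the whole pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
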