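Package: barcodeaudit
Title: Auditing DNA-Barcode Species Identification over COI Reference Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to audit species identifications obtained by nearest-sequence
    matching of COI DNA barcodes against a labeled reference library. Implements
    Kimura 2-parameter and p-distances with pairwise deletion, BOLD-style top-k
    similarity search with rank-escalating consensus identification, single-linkage
    cluster delimitation with nearest-neighbor distances, a six-category
    classification of problematic identifications (reference mislabels, cross-genus
    contamination, undifferentiated barcodes, unresolved taxonomy, anomalous
    haplotypes, database incompleteness), a geographic-correction rule for
    barcode-sharing species, cluster-level aggregation of audit results, and a
    synthetic reference-library generator that injects each error process at known
    rates with ground-truth labels for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
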