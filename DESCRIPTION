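Package: barcodefish
Title: Barcode Fishing for Lineage Assignment of Archival DNA Specimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reference-guided pipeline for assigning degraded archival-DNA
    specimens (e.g. century-old museum types) to candidate genetic lineages
    using short sequencing reads and a panel of mitochondrial barcode
    references. Reads are quality-trimmed and similarity-filtered against the
    panel ("barcode fishing"), a majority consensus is called in reference
    coordinates with per-position coverage, lineage-diagnostic alignment
    columns are scored against the partial consensus, and the consensus is
    placed with Tamura-Nei (TN93) distances, neighbor-joining trees and
    nonparametric bootstrap support. Includes a synthetic archival-read
    generator (fragmentation, terminal cytosine deamination, sequencing error,
    contamination, coverage dropout) so the whole pipeline is testable without
    external data, and a small module recomputing morphometric diagnostics and
    minimum-convex-polygon range areas from specimen tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils,
    grDevices,
    Biostrings,
    IRanges,
    ape,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
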