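Package: splitmol
Title: Large Structural Variant Discovery from Linked-Read Split Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers large structural variants (deletions, inversions,
    interspersed segmental duplications in direct and inverted orientation, and
    non-reciprocal translocations) from barcoded linked-read alignments. Large
    input molecules are reconstructed per barcode from concordant read-pair
    fragments, molecules split by a rearrangement are paired across barcodes
    into split-molecule signatures, signatures are clustered with a
    quasi-clique graph heuristic, and candidate calls are filtered with
    molecule-depth statistics. Ships a synthetic linked-read simulator with
    planted variants and an evaluation harness scoring calls against truth by
    reciprocal overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    stringr,
    data.table,
    igraph,
    jsonlite,
    withr,
    Rcpp,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Rsamtools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
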