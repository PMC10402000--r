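Package: isocloud
Title: De Novo Isoform Assembly from Barcoded Read-Cloud RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles full-length transcript isoforms from barcoded ("read
    cloud") bulk RNA-seq without a reference genome. All reads are first
    co-assembled into one compacted double-stranded de Bruijn graph; reads of
    each barcode are then aligned back to the graph, the alignment-induced
    subgraph is cleaned with cloud-local tip clipping, bulge removal and gap
    closing, and isoform paths are extracted with paired-end link support and
    clustered across barcodes to estimate per-isoform abundances from barcode
    counts. Includes barcode-aware filters, a simulator of spliced gene models
    and sparse barcoded read clouds with ground truth, and an evaluation module
    computing per-barcode precision, recall and fixed recall against the
    simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
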