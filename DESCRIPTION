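Package: bindnseq
Title: Motif Discovery and Peak Reanalysis for Bind-n-Seq Selection Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing barcoded Bind-n-Seq (in-vitro selection)
    sequencing libraries: demultiplexing by condition barcode, k-mer
    fold-enrichment over background, de-novo motif elicitation with a
    zero-or-one-occurrence-per-sequence (ZOOPS) EM refined by match-back
    rounds, position weight matrix scanning with exact dynamic-programming
    p-values, motif-motif comparison, and annotation of ChIP-seq peaks by
    distance to the nearest transcription start site with contingency tests
    of motif presence versus promoter proximity. Includes a parametric
    occupancy-based simulator of selection libraries and of synthetic
    genome/peak sets so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
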