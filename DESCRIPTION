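Package: vhrep
Title: Immunoglobulin Heavy-Chain Repertoire Analysis with a Synthetic Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for peripheral B-cell receptor heavy-chain (VH)
    repertoire analysis: UMI-based consensus building of amplicon reads,
    germline V/J assignment and junction extraction, clone definition by
    single-linkage clustering of length-normalized junction Hamming
    distances, bootstrap Hill-number diversity, somatic-hypermutation and
    gene-usage summaries, longitudinal clonal overlap, and matching of
    serum immunoglobulin proteome peptides to CDR3 regions of the
    transcriptome. A seeded synthetic repertoire generator emulates the
    statistical structure of sorted B-cell subsets so that every stage is
    verifiable against a known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
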