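Package: cemig
Title: De Novo Cis-Regulatory Motif Discovery on De Bruijn and Hamming
    Distance Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the CEMIG algorithm for de novo discovery of
    transcription-factor binding motifs in accessible-chromatin (ATAC-seq
    footprint) sequences. k-mers are scored for enrichment against a
    zero- to second-order Markov background with a Poisson model,
    partitioned into significance tiers, clustered on a Hamming-distance
    graph by greedy hill-climbing of an information-weighted objective,
    merged on a de Bruijn graph, and assembled into motifs by greedy path
    extension with occurrence-overlap refinement. Includes a synthetic
    planted-motif sequence generator with exact ground truth, sequence
    classification metrics (precision, specificity, accuracy, AUPRC), and
    writers for MEME minimal motif format and BED6 site lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
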