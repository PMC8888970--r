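Package: wesfusion
Title: Fusion Gene Detection from Whole-Exome and Targeted Panel DNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects gene fusions directly from DNA read alignments produced by
    whole-exome or targeted-panel sequencing. Candidate fusions are assembled
    from discordant read pairs and soft-clip/supplementary split reads, grouped
    into fusion equivalence classes at the transcript level, and passed through
    a cascade of filters (chromosome whitelist, protein-coding biotype,
    same-chromosome distance, minimum support, split-read gene count and
    mate-overlap rules) plus a simulation-based paralog filter that flags gene
    pairs whose transcripts share exactly mappable reads. A synthetic-data
    module generates toy references, planted-fusion paired-end alignments and
    coverage subsamples so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
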