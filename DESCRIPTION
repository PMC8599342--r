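Package: atacscreen
Title: Integrative ATAC-Seq and RNA-Seq Screening of Candidate Reprogramming Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a chromatin-accessibility and transcriptome screen for
    candidate cell-fate transcription factors. Tag alignments are filtered
    (mapping quality, mitochondrial removal, per-replicate deduplication),
    merged across replicates and turned into scaled coverage tracks; peaks are
    called against a Poisson background, classified into state-specific and
    shared groups, and linked to genes by TSS proximity. Peak groups are
    scanned with position weight matrices and per-motif enrichment of one
    group against the other is tested hypergeometrically. RNA-seq counts are
    GC-normalized, replicate-averaged and classified into state-specific
    highly expressed genes. Motif enrichment and differential expression are
    intersected to nominate and rank candidate factors. A synthetic-data
    module generates genomes with planted motif instances, contaminated ATAC
    tag libraries and negative-binomial count matrices with a known truth
    table, so the whole screen is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
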