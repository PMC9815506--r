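Package: epidiff
Title: Differential Epitranscriptome Analysis for Nanopore Direct RNA Sequencing
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Per-position differential RNA-modification calling between two
    conditions from nanopore direct RNA sequencing coverage/fraction tracks
    (pooled-replicate Fisher exact tests with a pseudocounted log2 fold change),
    RRACH m6A motif scanning with full-length and 5'UTR/CDS/3'UTR metagene
    profiles and kmer frequencies, poly(A) tail-length QC and summaries, CPM
    normalization with expression filtering, a cross-omics Pearson correlation
    suite and significant-set overlap reporting, plus a seeded synthetic-data
    generator with planted ground truth for end-to-end validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
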