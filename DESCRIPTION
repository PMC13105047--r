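Package: recsplice
Title: Recursive Splicing Detection and Sequence-Feature Analysis from
    Nascent RNA-Seq Splice Junctions
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies recursive splice junctions from nascent
    RNA-Seq splice-junction tables against constitutive introns, discovers
    flanking sequence features with positional k-mer latent Dirichlet
    allocation mixture models, quantifies first-exon CpG methylation and the
    coupling between first-intron and downstream-intron recursive splicing,
    trains random-forest classifiers of recursive splicing outcome, maps
    in-vitro RNA Bind-n-Seq k-mer preferences onto splice-site positions, and
    summarizes targeted primer-extension (LSV-seq) validation counts. A
    seeded synthetic-data generator emulates all pipeline inputs with planted
    signal so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ranger,
    pROC,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
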