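Package: mraxis
Title: Master-Regulator Inference, Enrichment and Somatic-Variant Filtering
    for Oncohistone-Driven Transcriptome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying candidate master-regulator transcription
    factors from differential-expression tables and TF-DNA / protein-protein
    interaction networks using a distance- and out-degree-weighted network
    score; pre-ranked gene set enrichment analysis (GSEA), single-sample GSEA
    and hypergeometric overlap statistics; two-caller somatic variant
    consensus filtering for matched and unmatched tumour designs with
    RAS/MAPK/PI3K and MYC pathway mutant classification; strand-oriented TSS
    metagene profiling of ChIP-seq coverage; and a synthetic-data generator
    that plants known regulators, enrichments, somatic variants and promoter
    depletion so that every stage can be exercised and validated without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
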