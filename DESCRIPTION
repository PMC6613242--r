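Package: vasculink
Title: Linking GWAS Variants to Genes Through Endothelial Chromatin
    Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An integrative regulatory-genomics toolkit modelled on the
    analysis of TNF-alpha-activated endothelial cells: classification of
    differentially expressed genes and differentially opened chromatin
    peaks, Knight-Ruiz balancing of Hi-C contact matrices, A/B compartment
    calling by per-chromosome principal component analysis with gene-density
    sign correction, insulation-score TAD boundary detection, enrichment of
    trait-associated SNPs in open chromatin with circular-shift and
    matched-SNP null models, and a filter cascade that links SNP-bearing
    open-chromatin peaks to gene promoters through chromatin-loop support
    and eQTL evidence. A synthetic-data module generates every pipeline
    input with planted ground truth so all callers can be scored without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
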