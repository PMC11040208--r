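Package: sweephap
Title: Selective-Sweep Scans and Promoter Tag-SNP Haplotype Analysis for
    Crop Resequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Windowed nucleotide diversity (pi) and pi-ratio selective-sweep
    scans across stratified population panels (wild, domesticated, improved),
    promoter variant extraction anchored on the ATG start codon, tag-SNP
    haplotype classification with group-wise frequency tables and
    permutation one-way ANOVA, neighbor-joining phylogenies with bootstrap
    supports, and a Wright-Fisher drift simulator that emits fully synthetic
    VCF/GFF3/FASTA/TSV fixtures so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    SummarizedExperiment,
    tools,
    utils,
    VariantAnnotation
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
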