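Package: fleshmark
Title: Flesh-Color Marker Development from Allele Panels of a Single Gene
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing PCR-based molecular markers that predict
    radish (Raphanus sativus) taproot flesh color from polymorphisms in a
    single anthocyanin-regulatory gene (the bHLH gene RsTT8). From a
    phenotype-labelled panel of cloned allele sequences the package aligns
    alleles to a reference, calls SNP, InDel and microsatellite (SSR)
    polymorphisms, classifies them by gene region and by group specificity
    (red-fleshed versus white-fleshed haplotype groups), builds a
    neighbor-joining allele tree, designs codominant length markers and
    dominant allele-specific primer pairs anchored on diagnostic sites,
    genotypes accessions by in-silico PCR, and reports genotype-phenotype
    concordance. A seeded synthetic allele-panel generator with a
    machine-readable truth set makes every stage testable without external
    sequence downloads. Spectrophotometric anthocyanin quantification
    helpers are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn
Config/testthat/edition: 3
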