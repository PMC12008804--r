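Package: ampliDel
Title: Focal Deletions Nested in Amplifications: Calling, Event Timing,
    and Gene-Dosage Expression Modelling
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying small (sub-100-kbp) somatic deletions that
    occur inside larger copy-number amplifications at a gene locus, as seen
    for BRD4 within CCNE1-driven chromosome 19 amplicons. Provides a
    synthetic tumor-cohort generator with a ground-truth ledger
    (copy-number segments, SV junctions, binned read-depth tracks, FPKM
    expression); a focal-deletion caller combining segment evidence,
    junction orientation, and a read-depth rescue pathway; allelic
    copy-number event-timing inference (amplification-first versus
    deletion-first) with an exact binomial enrichment test; and a
    copy-number-aware expression layer (dosage linear model, per-gene
    differential expression with Bonferroni and fold-change gates, exact
    rank-sum and Fisher tests, ORF-screen log-fold-change utilities).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: CopyNumberVariation, StructuralVariation, GeneExpression,
    Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
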