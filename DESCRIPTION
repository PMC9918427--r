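Package: splicedx
Title: Variant Prioritization and Splice-Consequence Interpretation for
    USH2A-Associated Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a whole-genome-sequencing variant interpretation
    workflow for suspected USH2A-associated Usher syndrome and autosomal
    recessive retinitis pigmentosa: allele-frequency and in-silico score
    triage of SNVs (Grantham, CADD, PhyloP, SpliceAI delta scores),
    structural-variant prioritization, selection of candidates for minigene
    splice assays, prediction of transcript- and protein-level consequences
    of splice events (pseudoexon inclusion, exon skipping, exon extension,
    partial and internal exon deletions) with HGVS protein nomenclature,
    assay-outcome-driven ACMG-style classification, and per-proband case
    resolution with cohort summaries. Includes seeded synthetic-data
    generators (transcripts, annotated variants, cohorts) so every stage is
    testable without external data, and an independent brute-force
    consequence oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
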