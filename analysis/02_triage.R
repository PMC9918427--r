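#!/usr/bin/env Rscript
# Step 2 -- variant triage on the synthetic VCF.
#
# Extracts the records overlapping the target regions, applies the allele
# frequency filter (<=1% everywhere) and the potentially-pathogenic criteria
# (retained categories; missense Grantham>=80 / CADD>=15 / PhyloP>=2.7;
# SpliceAI two scores >=0.1 or one >=0.15), and writes the triage report.

suppressPackageStartupMessages(library(splicedx))

src <- "results/synthetic"
stopifnot(file.exists(file.path(src, "variants.vcf")))
regions <- read_bed_regions(file.path(src, "regions.bed"))
variants <- extract_region_variants(file.path(src, "variants.vcf"), regions)
message(sprintf("extracted %d in-region records", nrow(variants)))

triaged <- triage_variants(variants, triage_config())
utils::write.table(triaged, "results/triage.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

message(sprintf("AF filter: %d/%d pass; triage retained %d (%s)",
                sum(triaged$af_pass), nrow(triaged), sum(triaged$retained),
                paste(sprintf("%s=%d",
                              names(table(unlist(strsplit(
                                triaged$reasons[triaged$retained], ";")))),
                              as.integer(table(unlist(strsplit(
                                triaged$reasons[triaged$retained], ";"))))),
                      collapse = ", ")))
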