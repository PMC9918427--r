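#!/usr/bin/env Rscript
# Step 1 -- synthetic study inputs.
#
# Generates everything the downstream steps need without external data: a
# minus-strand multi-exon transcript with full genomic sequence (the USH2A
# situation), an annotated variant table written as VCF 4.2, target regions
# as BED, and a 100-proband cohort with known expected statuses.

suppressPackageStartupMessages(library(splicedx))

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- sim_config(seed = 7, n_variants = 60)

tx <- make_transcript(cfg, id = "SYNTX1", strand = "-")
write_transcript_tsv(tx, file.path(out, "transcript.tsv"))
Biostrings::writeXStringSet(
  Biostrings::DNAStringSet(stats::setNames(tx$genome_seq, tx$chrom)),
  file.path(out, "transcript.fa"))
message(sprintf("transcript: %d exons, %d nt mature, CDS %d..%d, strand %s",
                n_exons(tx), tx$tx_length, tx$cds_start_c, tx$cds_end_c,
                tx$strand))

vars <- make_variant_table(sim_config(seed = 8, n_variants = 60), tx)
write_variant_vcf(vars, file.path(out, "variants.vcf"))
write_bed_regions(data.frame(chrom = tx$chrom,
                             start = min(tx$exon_starts) - 100,
                             end = max(tx$exon_ends) + 100),
                  file.path(out, "regions.bed"))
message(sprintf("variants: %d records over %s:%d-%d", nrow(vars), tx$chrom,
                min(vars$pos), max(vars$pos)))

coh <- make_cohort(sim_config(seed = 9))
utils::write.table(coh$cohort, file.path(out, "cohort.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("cohort: %d probands (expected: %s)", nrow(coh$cohort),
                paste(sprintf("%s=%d", names(table(coh$expected_status)),
                              as.integer(table(coh$expected_status))),
                      collapse = ", ")))
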