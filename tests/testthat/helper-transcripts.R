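# Deterministic three-exon test transcript (150 nt mature, CDS 10..129):
# 5' UTR of 9 C's, CDS = ATG + (Ala,Glu)x19 + TAA, 3' UTR starting with a
# stop cassette. Exons of 30/60/60 nt with 100 nt introns of fixed pattern.
# Built on either strand with identical spliced sequence.
mk_test_transcript <- function(strand = "+") {
  utr5 <- strrep("C", 9)
  cds <- paste0("ATG", strrep("GCTGAA", 19), "TAA")
  utr3 <- paste0("TTAATTAATTAA", strrep("C", 9))
  spliced <- paste0(utr5, cds, utr3)
  e1 <- substr(spliced, 1, 30)
  e2 <- substr(spliced, 31, 90)
  e3 <- substr(spliced, 91, 150)
  g <- paste0(e1, strrep("ACGT", 25), e2, strrep("TGCA", 25), e3)
  if (strand == "+") {
    transcript_model("TT1", "chrT", "+", c(1, 131, 291), c(30, 190, 350),
                     10, 129, g, 1)
  } else {
    gr <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
    transcript_model("TT1", "chrT", "-", c(321, 161, 1), c(350, 220, 60),
                     10, 129, gr, 1)
  }
}

expect_same_consequence <- function(engine, oracle) {
  expect_identical(engine$hgvs_p, oracle$hgvs_p)
  expect_identical(engine$effect_class, oracle$effect_class)
  expect_identical(engine$nmd_predicted, oracle$nmd_predicted)
}
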