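test_that("transcript model validates its invariants", {
  expect_error(transcript_model("x", "chr1", "+", c(10, 5), c(20, 8), 1, 9),
               "transcript order")
  expect_error(transcript_model("x", "chr1", "+", c(10), c(40), 1, 11),
               "divisible by 3")
  expect_error(transcript_model("x", "chr1", "+", c(30), c(10), 1, 9),
               "start <= end")
  tx <- mk_test_transcript("-")
  expect_identical(tx$tx_length, 150L)
  expect_identical(n_exons(tx), 3L)
})

test_that("cDNA positions map to genomic positions on both strands", {
  txp <- mk_test_transcript("+")
  # c.1 is the A of ATG at transcript position 10, exon 1
  expect_identical(c_to_genomic(txp, 1), 10L)
  # 5' UTR position
  expect_identical(c_to_genomic(txp, -9), 1L)
  # donor-side intronic offset from the last base of exon 1 (c.21)
  expect_identical(c_to_genomic(txp, 21, offset = 5), 35L)
  # acceptor-side offset from the first base of exon 2 (c.22)
  expect_identical(c_to_genomic(txp, 22, offset = -5), 126L)
  txm <- mk_test_transcript("-")
  # increasing cDNA positions run down the genome on the minus strand
  g <- vapply(1:10, function(cpos) c_to_genomic(txm, cpos), 1L)
  expect_true(all(diff(g) == -1L))
  # last transcript base lands on the genomic start of the last exon interval
  expect_identical(splicedx:::t_to_g(txm, txm$tx_length), txm$exon_starts[3])
})

test_that("offset walking past the neighbouring exon is an error", {
  tx <- mk_test_transcript("+")
  expect_error(c_to_genomic(tx, 21, offset = 101), "walks past")
  expect_error(c_to_genomic(tx, 22, offset = -101), "walks past")
  # offsets must anchor at exon boundaries
  expect_error(c_to_genomic(tx, 15, offset = 3), "non-boundary")
})

test_that("coordinate round trip is the identity on random transcripts", {
  set.seed(11)
  for (rep in 1:6) {
    tx <- make_transcript(sim_config(seed = NA, n_exons = 5), strand = "random")
    # exhaustive per-base check against a lookup table built by walking exons
    lut <- integer(0)
    for (k in seq_len(n_exons(tx))) {
      g <- tx$exon_starts[k]:tx$exon_ends[k]
      if (tx$strand == "-") g <- rev(g)
      lut <- c(lut, g)
    }
    t_all <- seq_len(tx$tx_length)
    expect_identical(splicedx:::t_to_g(tx, t_all), lut)
    for (t_pos in sample(t_all, 200)) {
      cc <- genomic_to_c(tx, lut[t_pos])
      expect_identical(cc$offset, 0L)
      expect_identical(c_to_genomic(tx, cc$pos, star = cc$star), lut[t_pos])
    }
    # intronic positions anchor to the nearer boundary and invert correctly
    if (n_exons(tx) > 1) {
      for (i in 1:25) {
        gmin <- min(tx$exon_starts); gmax <- max(tx$exon_ends)
        g <- sample(setdiff(seq(gmin, gmax), unlist(mapply(seq, tx$exon_starts,
                                                           tx$exon_ends))), 1)
        cc <- genomic_to_c(tx, g)
        expect_true(cc$offset != 0L)
        expect_identical(c_to_genomic(tx, cc$pos, cc$offset, cc$star), g)
      }
    }
  }
})

test_that("interval length matches the printed pseudoexon sizes", {
  expect_identical(interval_length(216495824, 216495941), 118L)
  expect_identical(interval_length(216352719, 216352805), 87L)
  expect_identical(interval_length(5, 5), 1L)
  expect_error(interval_length(10, 5), "end before start")
  # additivity over a partition
  expect_identical(interval_length(100, 149) + interval_length(150, 200),
                   interval_length(100, 200))
})

test_that("transcript TSV and GFF3 readers round-trip the model", {
  tx <- mk_test_transcript("-")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fa")
  write_transcript_tsv(tx, tsv)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(tx$genome_seq, "chrT")), fa)
  back <- read_transcript_tsv(tsv, fa)
  expect_identical(back$exon_starts, tx$exon_starts)
  expect_identical(back$strand, tx$strand)
  expect_identical(spliced_sequence(back), spliced_sequence(tx))

  gff <- withr::local_tempfile(fileext = ".gff3")
  ex_lines <- sprintf(
    "chrT\ttest\texon\t%d\t%d\t.\t-\t.\tID=TT1.e%d;Parent=TT1",
    sort(tx$exon_starts), sort(tx$exon_ends), 1:3)
  cds_g1 <- splicedx:::t_to_g(tx, tx$cds_start_c); cds_g2 <- splicedx:::t_to_g(tx, tx$cds_end_c)
  cds_line <- sprintf("chrT\ttest\tCDS\t%d\t%d\t.\t-\t.\tParent=TT1",
                      min(cds_g1, cds_g2), max(cds_g1, cds_g2))
  writeLines(c("##gff-version 3", ex_lines, cds_line), gff)
  back2 <- read_transcript_gff3(gff, fa)
  expect_identical(back2$exon_starts, tx$exon_starts)
  expect_identical(back2$cds_start_c, tx$cds_start_c)
  expect_identical(back2$cds_end_c, tx$cds_end_c)
})
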