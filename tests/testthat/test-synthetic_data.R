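test_that("generation is deterministic under a fixed seed", {
  t1 <- make_transcript(sim_config(seed = 5))
  t2 <- make_transcript(sim_config(seed = 5))
  expect_identical(t1$genome_seq, t2$genome_seq)
  expect_identical(t1$exon_starts, t2$exon_starts)
  expect_identical(t1$strand, t2$strand)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_transcript_tsv(t1, f1); write_transcript_tsv(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  v1 <- make_variant_table(sim_config(seed = 9))
  v2 <- make_variant_table(sim_config(seed = 9))
  expect_identical(v1, v2)
  c1 <- make_cohort(sim_config(seed = 13))
  c2 <- make_cohort(sim_config(seed = 13))
  expect_identical(c1, c2)
})

test_that("generated transcripts have a clean CDS on either strand", {
  for (seed in 1:6) {
    tx <- make_transcript(sim_config(seed = seed))
    sp <- spliced_sequence(tx)
    cds <- substr(sp, tx$cds_start_c, tx$cds_end_c)
    expect_identical(nchar(cds) %% 3L, 0L)
    expect_identical(substr(cds, 1, 3), "ATG")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    # direct translation scan: single terminal stop, no internal stop
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("planted events carry the oracle ground truth", {
  set.seed(77)
  tx <- make_transcript(sim_config(seed = NA))
  for (i in 1:10) {
    pl <- plant_splice_event(tx, sim_config(seed = NA))
    expect_s3_class(pl$event, "splice_event")
    expect_true(pl$truth$effect_class %in%
                c("ptc_frameshift", "ptc_in_inserted", "inframe_deletion",
                  "inframe_insertion", "no_change"))
  }
  # an in-frame skip is deletion-class by construction
  skel <- plant_splice_event(tx, sim_config(seed = NA), types = "exon_skip")
  if (abs(event_size(tx, skel$event)) %% 3L == 0L)
    expect_identical(skel$truth$effect_class, "inframe_deletion")
})

test_that("synthetic cohorts recover the mixture's expected statuses", {
  out <- make_cohort(sim_config(seed = 101, n_probands = 400))
  expect_identical(nrow(out$cohort), 400L)
  got <- vapply(seq_len(400), function(i)
    resolve_case(out$cohort$class1[i], out$cohort$class2[i]), "")
  expect_identical(got, out$expected_status)
  # solved frequency within binomial error of the mixture expectation:
  # plp_pair (0.37) always solves; nothing else can
  p <- 0.37
  se <- sqrt(p * (1 - p) / 400)
  expect_lt(abs(mean(got == "solved") - p), 4 * se)
  # concentrated weights behave degenerately
  all_solved <- make_cohort(sim_config(
    seed = 7, n_probands = 40,
    mixture_weights = c(plp_pair = 1, plp_vus = 0, vus_vus = 0,
                        benign_pair = 0, mono = 0, none = 0)))
  expect_true(all(all_solved$expected_status == "solved"))
  empty <- make_cohort(sim_config(seed = 7, n_probands = 0))
  expect_identical(nrow(empty$cohort), 0L)
})

test_that("generated VCF validates and re-parses losslessly", {
  tx <- make_transcript(sim_config(seed = 19))
  vars <- make_variant_table(sim_config(seed = 19, n_variants = 30), tx)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(vars, vcf)
  back <- extract_region_variants(vcf)
  expect_identical(nrow(back), 30L)
  expect_identical(back$pos, vars$pos)
  expect_identical(back$category, vars$category)
  expect_equal(back$af_global, vars$af_global)
  expect_equal(back$ds_ag, vars$ds_ag)
  expect_equal(back$af_subpops, vars$af_subpops)
})
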