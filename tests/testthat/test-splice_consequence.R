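test_that("apply_event keeps exact length accounting", {
  for (st in c("+", "-")) {
    tx <- mk_test_transcript(st)
    skip <- splice_event("exon_skip", exon = 2)
    mut <- apply_event(tx, skip)
    expect_identical(nchar(mut$seq), tx$tx_length - 60L)
    pe <- if (st == "+")
      splice_event("pseudoexon_inclusion", pe_start = 41, pe_end = 127)
    else
      splice_event("pseudoexon_inclusion", pe_start = 350 - 127 + 1,
                   pe_end = 350 - 41 + 1)
    mut <- apply_event(tx, pe)   # an 87 nt pseudoexon
    expect_identical(nchar(mut$seq), tx$tx_length + 87L)
    # non-event sequence is conserved around the insertion
    expect_identical(substr(mut$seq, 1, 30), substr(spliced_sequence(tx), 1, 30))
  }
})

test_that("a pseudoexon outside any intron is a coordinate error", {
  tx <- mk_test_transcript("+")
  expect_error(apply_event(tx, splice_event("pseudoexon_inclusion",
                                            pe_start = 25, pe_end = 45)),
               "not contained in any intron")
})

test_that("frame effect is size modulo three", {
  expect_identical(frame_effect(87), "in_frame")
  expect_identical(frame_effect(130), "frameshift")
  expect_identical(frame_effect(3), "in_frame")
  expect_error(frame_effect(0), ">= 1")
  expect_error(splice_event("pseudoexon_inclusion", pe_start = 0, pe_end = 10),
               "count >= 1")
})

test_that("event consequences match frozen oracle values on both strands", {
  # expectations computed once with bf_splice_consequence on the
  # deterministic helper transcript and frozen here
  frozen <- list(
    list(ev = function(st) splice_event("exon_skip", exon = 2),
         p = "Ala20_Glu39del", cls = "inframe_deletion"),
    list(ev = function(st) splice_event("exon_extension_3", exon = 1,
                                        extension_nt = 7),
         p = "Ala8Thrfs*4", cls = "ptc_frameshift"),
    list(ev = function(st) splice_event("exon_extension_5", exon = 2,
                                        extension_nt = 8),
         p = "Ala8Thrfs*37", cls = "ptc_frameshift"),
    list(ev = function(st) if (st == "+")
           splice_event("pseudoexon_inclusion", pe_start = 41, pe_end = 70)
         else
           splice_event("pseudoexon_inclusion", pe_start = 350 - 70 + 1,
                        pe_end = 350 - 41 + 1),
         p = "Glu7_Ala8insValArgThrTyrValArgThrTyrValArg",
         cls = "inframe_insertion"),
    list(ev = function(st) splice_event("partial_exon_skip", exon = 2,
                                        deleted_nt = 6, side = "3"),
         p = "Ala38_Glu39del", cls = "inframe_deletion"),
    list(ev = function(st) splice_event("exon_internal_deletion", exon = 2,
                                        novel_donor_offset = 12,
                                        novel_acceptor_offset = 9),
         p = "Ala12_Ala24del", cls = "inframe_deletion"))
  for (st in c("+", "-")) {
    tx <- mk_test_transcript(st)
    for (case in frozen) {
      got <- predict_protein_consequence(tx, case$ev(st))
      expect_identical(got$hgvs_p, case$p)
      expect_identical(got$effect_class, case$cls)
    }
  }
})

test_that("frame determines the consequence family", {
  set.seed(31)
  n_inframe_del <- 0; n_shift <- 0
  deletion_types <- c("exon_skip", "partial_exon_skip",
                      "exon_internal_deletion")
  while (n_inframe_del < 30 || n_shift < 30) {
    tx <- make_transcript(sim_config(seed = NA), strand = "random")
    pl <- plant_splice_event(tx, sim_config(seed = NA))
    size <- event_size(tx, pl$event)
    got <- suppressWarnings(predict_protein_consequence(tx, pl$event))
    if (size %% 3L == 0L && pl$event$type %in% deletion_types) {
      # in-frame deletions never read as fs*/ins*
      expect_false(grepl("fs\\*|ins\\*", got$hgvs_p))
      expect_false(got$effect_class == "ptc_in_inserted")
      n_inframe_del <- n_inframe_del + 1
    } else if (size %% 3L != 0L) {
      # frameshifts always end in a PTC-class consequence (a downstream
      # stop always exists on these transcripts)
      expect_true(got$effect_class %in% c("ptc_frameshift",
                                          "ptc_in_inserted"))
      n_shift <- n_shift + 1
    }
  }
})

test_that("outcomes serialise with multi-effect brackets and residual '='", {
  tx <- mk_test_transcript("+")
  two <- splice_outcome("c.1X>Y", list(
    splice_event("exon_skip", exon = 2),
    splice_event("partial_exon_skip", exon = 2, deleted_nt = 6, side = "3")),
    conventional_transcript_present = TRUE)
  cons <- consequence_for_outcome(tx, two)
  expect_length(cons, 3)
  expect_identical(cons[[3]]$hgvs_p, "=")
  expect_identical(format_consequences(cons),
                   "p.[Ala20_Glu39del,Ala38_Glu39del,=]")
  one <- splice_outcome("c.2X>Y", list(splice_event("exon_skip", exon = 2)))
  expect_identical(format_consequences(consequence_for_outcome(tx, one)),
                   "p.Ala20_Glu39del")
  expect_identical(format_consequences(consequence_for_outcome(tx, one),
                                       observed = FALSE),
                   "p.(Ala20_Glu39del)")
  conv <- splice_outcome("c.3X>Y", conventional_transcript_present = TRUE)
  expect_identical(format_consequences(consequence_for_outcome(tx, conv)),
                   "p.=")
  expect_error(splice_outcome("c.4X>Y"), "at least one event")
  expect_true(is_full_effect(one))
  expect_false(is_full_effect(two))
})
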