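test_that("parse_hgvs covers every construct in the study tables", {
  v <- parse_hgvs("c.2299del")
  expect_identical(v$kind, "deletion")
  expect_identical(v$pos1$base, 2299L)
  expect_null(v$pos2)

  v <- parse_hgvs("c.4397-3890A>G")
  expect_identical(v$kind, "substitution")
  expect_identical(v$pos1$base, 4397L)
  expect_identical(v$pos1$offset, -3890L)
  expect_identical(v$ref, "A")
  expect_false(isTRUE(v$no_change))

  # identity substitution is accepted and flagged
  expect_true(parse_hgvs("c.1A>A")$no_change)

  v <- parse_hgvs("c.4627+25436_4987+659del")
  expect_identical(v$kind, "deletion")
  expect_identical(v$pos2$offset, 659L)

  v <- parse_hgvs("g.42320825_215677220delins42320846_215677215inv")
  expect_identical(v$kind, "delins")
  expect_identical(v$inv_range, c(42320846L, 215677215L))

  v <- parse_hgvs("c.-12233_-447-18280del")
  expect_identical(v$pos1$base, -12233L)
  expect_identical(v$pos2$base, -447L)
  expect_identical(v$pos2$offset, -18280L)

  v <- parse_hgvs("c.[2276G>T(;)4618G>A]")
  expect_identical(v$kind, "compound")
  expect_length(v$components, 2)

  # internal whitespace is normalised away
  expect_identical(format_hgvs(parse_hgvs("c.705-3940_ 982+2952del")),
                   "c.705-3940_982+2952del")

  expect_error(parse_hgvs("p.Arg100Cys"), "begin 'c.' or 'g.'")
  expect_error(parse_hgvs("c.12x>y"), "cannot parse")
})

test_that("parsing then serialising reproduces every fixture variant string", {
  co <- read_cohort_tsv(splicedx_fixture("study_cohort.tsv"))
  cand <- read.delim(splicedx_fixture("splice_candidates.tsv"))
  out <- read_outcome_table(splicedx_fixture("assay_outcomes.tsv"))
  vs <- stats::na.omit(c(co$variant1, co$variant2, cand$variant, out$variant))
  expect_gt(length(vs), 150)
  for (v in vs) expect_identical(format_hgvs(parse_hgvs(v)), v)
})

test_that("SV typing follows the del/dup/inv mapping and recounts the table", {
  expect_identical(sv_type_from_hgvs("c.2994-3030_14343+488dup"), "duplication")
  expect_identical(sv_type_from_hgvs("g.209815568_215637482inv"), "inversion")
  expect_identical(sv_type_from_hgvs("c.9335_9371+8063delinsGAAGACACTCC"),
                   "deletion")
  expect_identical(
    sv_type_from_hgvs("g.42320825_215677220delins42320846_215677215inv"),
    "inversion")
})

test_that("structural calls are separated from small indels by span", {
  expect_false(is_structural(parse_hgvs("c.13335_13343del")))   # 9 nt
  expect_false(is_structural(parse_hgvs("c.15063_15081delinsGC")))
  expect_true(is_structural(parse_hgvs("c.8655_8681+1681del")))
  expect_true(is_structural(parse_hgvs("g.209815568_215637482inv")))
  expect_false(is_structural(parse_hgvs("c.2299del")))
})
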