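test_that("assay classification follows the full/partial-effect rules", {
  # full PTC effect in all transcripts -> pathogenic
  expect_identical(classify_from_assay(effect_classes = "ptc_in_inserted",
                                       conventional_present = FALSE)$label,
                   "pathogenic")
  # full in-frame deletion disrupting a domain -> likely pathogenic
  expect_identical(classify_from_assay(effect_classes = "inframe_deletion",
                                       conventional_present = FALSE,
                                       domain_disrupted = TRUE)$label,
                   "likely_pathogenic")
  # remaining conventional transcript -> VUS
  expect_identical(classify_from_assay(effect_classes = "ptc_frameshift",
                                       conventional_present = TRUE)$label,
                   "vus")
  # full in-frame effect without domain annotation -> VUS with warning
  expect_warning(
    lbl <- classify_from_assay(effect_classes = "inframe_deletion",
                               conventional_present = FALSE)$label,
    "domain")
  expect_identical(lbl, "vus")
  # no splice effect -> not reclassified
  expect_true(is.na(classify_from_assay(effect_classes = character(0),
                                        conventional_present = TRUE)$label))
})

test_that("assay classification accepts engine outcomes end to end", {
  tx <- mk_test_transcript("+")
  full_skip <- splice_outcome("c.x", list(splice_event("exon_skip", exon = 2)))
  cons <- consequence_for_outcome(tx, full_skip)
  expect_identical(classify_from_assay(full_skip, cons,
                                       domain_disrupted = TRUE)$label,
                   "likely_pathogenic")
  partial <- splice_outcome("c.y", list(splice_event("exon_skip", exon = 2)),
                            conventional_transcript_present = TRUE)
  expect_identical(
    classify_from_assay(partial, consequence_for_outcome(tx, partial))$label,
    "vus")
})

test_that("case resolution agrees with enumeration over all ordered pairs", {
  tab <- resolve_case_oracle_table()
  expect_identical(nrow(tab), 36L)   # five levels plus missing, squared
  for (i in seq_len(nrow(tab)))
    expect_identical(resolve_case(tab$class1[i], tab$class2[i]),
                     tab$status[i])
  # printed-label forms normalise the same way
  expect_identical(resolve_case("Pathogenic", "Likely pathogenic"), "solved")
  expect_identical(resolve_case("Pathogenic", "VUS"), "possibly_solved")
  expect_identical(resolve_case("VUS", "VUS"), "unsolved")
  expect_identical(resolve_case("Pathogenic", NA), "unsolved")
  # a VUS not deemed potentially causative does not support the case
  expect_identical(resolve_case("Pathogenic", "VUS", vus_causative2 = FALSE),
                   "unsolved")
})

test_that("upgrading an allele classification never lowers case status", {
  rank <- stats::setNames(seq_along(c("unsolved", "possibly_solved", "solved")),
                          c("unsolved", "possibly_solved", "solved"))
  lv <- c("benign", "likely_benign", "vus", "likely_pathogenic", "pathogenic")
  for (fixed in c(lv, NA_character_)) {
    stats_seq <- vapply(lv, function(x) resolve_case(fixed, x), "")
    expect_true(all(diff(rank[stats_seq]) >= 0))
  }
})

test_that("cohort resolution reproduces the published per-proband verdicts", {
  co <- resolve_cohort(read_cohort_tsv(splicedx_fixture("study_cohort.tsv")))
  expect_identical(nrow(co), 100L)
  map <- c("Possibly solved" = "possibly_solved", "Solved" = "solved",
           "Unsolved" = "unsolved")
  expect_identical(co$status, unname(map[co$status_printed]))
})

test_that("cohort summary partitions the cohort and rounds half-up", {
  co <- resolve_cohort(read_cohort_tsv(splicedx_fixture("study_cohort.tsv")))
  s <- cohort_summary(co)
  expect_identical(s$overall$solved + s$overall$possibly_solved,
                   s$overall$resolved)
  # statuses partition overall and within each phenotype
  expect_identical(sum(co$status %in% c("solved", "possibly_solved", "unsolved")),
                   nrow(co))
  expect_identical(sum(s$by_phenotype$n), s$overall$n)
  by_ph <- s$by_phenotype
  expect_identical(by_ph$pct_resolved[by_ph$phenotype == "USH"], 61)
  empty <- cohort_summary(data.frame())
  expect_identical(empty$overall$n, 0L)
  expect_identical(empty$overall$resolved, 0L)
})

test_that("SV accounting finds the published alleles and a trivial case", {
  co <- read_cohort_tsv(splicedx_fixture("study_cohort.tsv"))
  sv <- count_sv_alleles(co)
  expect_identical(sv$n_unique, 12L)
  expect_identical(sv$n_alleles, 13L)
  one <- data.frame(id = "USH99", causal_gene = "USH2A",
                    variant1 = "c.8655_8681+1681del", variant2 = NA,
                    class1 = "Pathogenic", class2 = NA)
  sv1 <- count_sv_alleles(one)
  expect_identical(c(sv1$n_unique, sv1$n_alleles), c(1L, 1L))
})
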