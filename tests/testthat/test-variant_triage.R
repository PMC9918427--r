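test_that("allele-frequency filter applies to every subpopulation inclusively", {
  cfg <- triage_config()
  expect_true(passes_af_filter(0.005, c(0.002, 0.009), cfg))
  expect_false(passes_af_filter(0.005, c(0.02), cfg))
  expect_true(passes_af_filter(0.010, numeric(0), cfg))   # boundary
  expect_true(passes_af_filter(NA, numeric(0), cfg))      # absent from gnomAD
  expect_error(passes_af_filter(1.2), "\\[0, 1\\]")
})

test_that("SpliceAI rule matches its printed two-branch form", {
  expect_true(meets_spliceai_rule(c(0.12, 0.11, 0.00, 0.00)))
  expect_true(meets_spliceai_rule(c(0.16, 0.00, 0.00, 0.00)))
  expect_false(meets_spliceai_rule(c(0.14, 0.09, 0.00, 0.00)))
  expect_warning(res <- meets_spliceai_rule(c(0.5, NA, 0, 0)), "missing")
  expect_false(res)
  expect_error(meets_spliceai_rule(c(0.1, 0.1, 0.1)), "four")
})

test_that("SpliceAI rule equals brute-force enumeration over a score grid", {
  vals <- c(0, 0.09, 0.1, 0.14, 0.15, 1)
  grid <- expand.grid(a = vals, b = vals, c = vals, d = vals)
  for (i in seq_len(nrow(grid))) {
    d <- as.numeric(grid[i, ])
    expect_identical(meets_spliceai_rule(d),
                     sum(d >= 0.1) >= 2 || any(d >= 0.15))
  }
})

test_that("SNV triage retains the printed categories and missense OR-clause", {
  expect_true(triage_snv("stop_gain")$retained)
  expect_identical(triage_snv("stop_gain")$reasons, "category")
  # all scores just below their thresholds
  low <- triage_snv("missense", grantham = 79, cadd_phred = 14, phylop = 2.6,
                    spliceai = c(0, 0, 0, 0))
  expect_false(low$retained)
  # splice rule rescues a weak missense
  spl <- triage_snv("missense", grantham = 5, cadd_phred = 0, phylop = 0,
                    spliceai = c(0.15, 0, 0, 0))
  expect_true(spl$retained)
  expect_identical(spl$reasons, "spliceai")
  # inclusive thresholds, reasons accumulate
  hit <- triage_snv("missense", grantham = 80, cadd_phred = 15, phylop = 2.7,
                    spliceai = c(0, 0, 0, 0))
  expect_setequal(hit$reasons,
                  c("missense_grantham", "missense_cadd", "missense_phylop"))
  expect_identical(triage_snv("weird_category")$reasons, "uncategorised")
})

test_that("SV prioritization applies quality, AF and exon-overlap rules", {
  expect_true(prioritize_sv(TRUE, 100, 0, 1))     # inclusive boundary
  expect_false(prioritize_sv(TRUE, 99, 0, 1))
  expect_false(prioritize_sv(FALSE, 500, 0, 1))
  expect_false(prioritize_sv(TRUE, 500, 0.02, 1))
  expect_false(prioritize_sv(TRUE, 500, 0, 0))
  expect_error(prioritize_sv(TRUE, 1500, 0, 1), "\\[0, 1000\\]")
})

test_that("minigene selection removes each excluded class in input order", {
  cand <- read.delim(splicedx_fixture("splice_candidates.tsv"))
  sel <- select_for_minigene(cand)
  expect_identical(nrow(sel), 21L)
  counts <- attr(sel, "excluded_counts")
  expect_identical(unname(counts[c("is_stop_gain", "is_canonical",
                                   "previously_characterized", "is_artifact",
                                   "remains_monoallelic",
                                   "predicts_canonical_gain")]),
                   c(2, 7, 3, 1, 1, 1))
  expect_identical(sel$variant, cand$variant[rowSums(cand[, 2:7]) == 0])

  empty <- select_for_minigene(cand[0, ])
  expect_identical(nrow(empty), 0L)
  all_prev <- cand
  all_prev$previously_characterized <- 1
  expect_identical(nrow(select_for_minigene(all_prev)), 0L)
})

test_that("filters are monotone under threshold tightening", {
  set.seed(21)
  variants <- make_variant_table(sim_config(seed = NA, n_variants = 120))
  base <- triage_variants(variants, triage_config())
  tighter <- list(
    triage_config(af_max = 0.001),
    triage_config(grantham_min = 150),
    triage_config(cadd_min = 30),
    triage_config(phylop_min = 6),
    triage_config(spliceai_single_min = 0.5, spliceai_pair_min = 0.3))
  for (cfg in tighter) {
    res <- triage_variants(variants, cfg)
    expect_true(all(which(res$retained) %in% which(base$retained)))
  }
  # no AF-failing variant is ever retained
  expect_true(all(base$af_pass[base$retained]))
})
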