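#' Triage configuration
#'
#' Thresholds for SNV and SV prioritization. Defaults are the published
#' cutoffs: gnomAD allele frequency <= 1% in the general population and every
#' subpopulation; missense retained when Grantham >= 80, CADD_PHRED >= 15 or
#' PhyloP >= 2.7; putative splice-modulating variants retained when two of the
#' four SpliceAI delta scores are >= 0.1 or one is >= 0.15; SVs retained when
#' they pass the caller QC, have quality >= 100 (of 1,000), AF <= 1% and
#' overlap at least one panel-gene exon. All comparisons are inclusive.
#'
#' @param af_max maximum allele frequency (global and per subpopulation).
#' @param grantham_min,cadd_min,phylop_min missense score thresholds (OR-ed).
#' @param spliceai_single_min single-score SpliceAI threshold.
#' @param spliceai_pair_min two-of-four SpliceAI threshold; must not exceed
#'   `spliceai_single_min`.
#' @param sv_quality_min minimum SV quality score.
#' @param target_regions optional [GenomicRanges::GRanges] of target regions.
#' @param gene_panels optional character vector of panel gene symbols.
#' @return a `triage_config` list.
#' @export
triage_config <- function(af_max = 0.01, grantham_min = 80, cadd_min = 15,
                          phylop_min = 2.7, spliceai_single_min = 0.15,
                          spliceai_pair_min = 0.1, sv_quality_min = 100,
                          target_regions = NULL, gene_panels = NULL) {
  stopifnot(af_max > 0, grantham_min > 0, cadd_min > 0, phylop_min > 0,
            spliceai_single_min > 0, spliceai_pair_min > 0, sv_quality_min > 0)
  if (spliceai_pair_min > spliceai_single_min)
    stop("spliceai_pair_min must not exceed spliceai_single_min")
  structure(list(af_max = af_max, grantham_min = grantham_min,
                 cadd_min = cadd_min, phylop_min = phylop_min,
                 spliceai_single_min = spliceai_single_min,
                 spliceai_pair_min = spliceai_pair_min,
                 sv_quality_min = sv_quality_min,
                 target_regions = target_regions, gene_panels = gene_panels),
            class = "triage_config")
}

SNV_CATEGORIES <- c("stop_gain", "frameshift", "inframe_indel",
                    "canonical_splice", "missense", "synonymous", "intronic",
                    "regulatory")
CATEGORY_RETAINED <- c("stop_gain", "frameshift", "inframe_indel",
                       "canonical_splice")

#' Population allele-frequency filter
#'
#' A variant passes when its global AF and the AF in every subpopulation are
#' all at or below `cfg$af_max` (inclusive). A variant absent from the
#' frequency database (NA) is treated as AF 0 and passes.
#'
#' @param af_global global allele frequency (fraction).
#' @param af_subpops numeric vector of subpopulation allele frequencies
#'   (possibly empty).
#' @param cfg a [triage_config()].
#' @return logical.
#' @export
passes_af_filter <- function(af_global, af_subpops = numeric(0),
                             cfg = triage_config()) {
  af <- c(af_global, af_subpops)
  af <- af[!is.na(af)]
  if (any(af < 0 | af > 1)) stop("allele frequencies must lie in [0, 1]")
  all(af <= cfg$af_max)
}

#' SpliceAI decision rule
#'
#' TRUE when two of the four delta scores (acceptor gain, acceptor loss, donor
#' gain, donor loss) are >= 0.1 or any one score is >= 0.15 (inclusive,
#' configurable). Missing scores make the rule evaluate FALSE with a warning.
#'
#' @param deltas numeric vector of four SpliceAI delta scores in \[0, 1\].
#' @param cfg a [triage_config()].
#' @return logical.
#' @examples
#' meets_spliceai_rule(c(0.12, 0.11, 0, 0))  # TRUE (two-of-four branch)
#' meets_spliceai_rule(c(0.14, 0.09, 0, 0))  # FALSE
#' @export
meets_spliceai_rule <- function(deltas, cfg = triage_config()) {
  if (length(deltas) != 4) stop("expected four SpliceAI delta scores")
  if (anyNA(deltas)) {
    warning("missing SpliceAI scores; rule evaluates FALSE")
    return(FALSE)
  }
  if (any(deltas < 0 | deltas > 1)) stop("SpliceAI delta scores must lie in [0, 1]")
  sum(deltas >= cfg$spliceai_pair_min) >= 2 ||
    max(deltas) >= cfg$spliceai_single_min
}

#' Triage a single SNV
#'
#' Applies the potentially-pathogenic criteria to an allele-frequency-filtered
#' SNV: (1) stop gain, frameshift, in-frame insertion/deletion or canonical
#' splice-site variants are retained by category; (2) missense variants are
#' retained when Grantham >= 80 OR CADD_PHRED >= 15 OR PhyloP >= 2.7 (missing
#' scores fail their clause); (3) any variant meeting the SpliceAI rule is
#' retained. Reasons list every satisfied clause. An unknown category is
#' rejected with reason `"uncategorised"`.
#'
#' @param category one of the recognised SNV categories.
#' @param grantham,cadd_phred,phylop missense scores (NA when absent).
#' @param spliceai numeric vector of four delta scores (NAs allowed; the
#'   splice clause then evaluates FALSE with a warning).
#' @param cfg a [triage_config()].
#' @return list with `retained` (logical) and `reasons` (character vector).
#' @export
triage_snv <- function(category, grantham = NA, cadd_phred = NA, phylop = NA,
                       spliceai = rep(NA_real_, 4), cfg = triage_config()) {
  if (!category %in% SNV_CATEGORIES)
    return(list(retained = FALSE, reasons = "uncategorised"))
  reasons <- character(0)
  if (category %in% CATEGORY_RETAINED) reasons <- c(reasons, "category")
  if (category == "missense") {
    if (!is.na(grantham) && grantham >= cfg$grantham_min)
      reasons <- c(reasons, "missense_grantham")
    if (!is.na(cadd_phred) && cadd_phred >= cfg$cadd_min)
      reasons <- c(reasons, "missense_cadd")
    if (!is.na(phylop) && phylop >= cfg$phylop_min)
      reasons <- c(reasons, "missense_phylop")
  }
  splice_hit <- if (anyNA(spliceai)) FALSE
                else meets_spliceai_rule(spliceai, cfg)
  if (splice_hit) reasons <- c(reasons, "spliceai")
  list(retained = length(reasons) > 0, reasons = reasons)
}

#' Triage a table of annotated SNVs
#'
#' Data-frame wrapper around [passes_af_filter()] and [triage_snv()]. The
#' input must carry columns `category`, `af_global`, and may carry
#' `af_subpops` (comma-separated string), `grantham`, `cadd_phred`, `phylop`,
#' `ds_ag`, `ds_al`, `ds_dg`, `ds_dl`. Variants failing the AF filter are
#' dropped before the category/score criteria so they can never surface
#' downstream.
#'
#' @param variants data frame of annotated variants.
#' @param cfg a [triage_config()].
#' @return the input with logical columns `af_pass`, `retained` and a
#'   character column `reasons` (`";"`-separated); rows failing the AF filter
#'   keep `retained = FALSE`.
#' @export
triage_variants <- function(variants, cfg = triage_config()) {
  n <- nrow(variants)
  col <- function(name) if (name %in% names(variants)) variants[[name]]
                        else rep(NA_real_, n)
  subpops <- if ("af_subpops" %in% names(variants))
    lapply(variants$af_subpops, function(s) {
      if (is.na(s) || !nzchar(s)) numeric(0)
      else as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
    })
  else rep(list(numeric(0)), n)
  af_pass <- vapply(seq_len(n), function(i)
    passes_af_filter(col("af_global")[i], subpops[[i]], cfg), TRUE)
  retained <- logical(n); reasons <- character(n)
  for (i in seq_len(n)) {
    if (!af_pass[i]) { reasons[i] <- "af_fail"; next }
    res <- triage_snv(variants$category[i], col("grantham")[i],
                      col("cadd_phred")[i], col("phylop")[i],
                      c(col("ds_ag")[i], col("ds_al")[i], col("ds_dg")[i],
                        col("ds_dl")[i]), cfg)
    retained[i] <- res$retained
    reasons[i] <- paste(res$reasons, collapse = ";")
  }
  variants$af_pass <- af_pass
  variants$retained <- retained
  variants$reasons <- reasons
  variants
}

#' Prioritize a structural/copy-number variant call
#'
#' Retained when the call passed the caller's internal QC, has quality >= 100
#' (of 1,000), AF <= 1% and overlaps at least one exon of a panel gene. All
#' thresholds inclusive; vectorised.
#'
#' @param qc_pass logical internal-QC flag.
#' @param quality caller quality score in \[0, 1000\].
#' @param af allele frequency in population SV databases (NA treated as 0).
#' @param exon_overlap number of panel-gene exons overlapped.
#' @param cfg a [triage_config()].
#' @return logical vector.
#' @export
prioritize_sv <- function(qc_pass, quality, af, exon_overlap,
                          cfg = triage_config()) {
  if (any(quality < 0 | quality > 1000, na.rm = TRUE))
    stop("SV quality scores must lie in [0, 1000]")
  af <- ifelse(is.na(af), 0, af)
  qc_pass & quality >= cfg$sv_quality_min & af <= cfg$af_max & exon_overlap >= 1
}

MINIGENE_EXCLUSION_FLAGS <- c("is_stop_gain", "is_canonical",
                              "previously_characterized", "is_artifact",
                              "remains_monoallelic", "predicts_canonical_gain")

#' Select splice candidates for minigene assays
#'
#' From the SpliceAI-flagged candidate list (plus any manual pre-SpliceAI
#' additions), removes variants in each excluded class: stop gain and
#' canonical splice-site variants (considered pathogenic without an assay),
#' variants whose splice effect was previously characterized, sequencing
#' artifacts, variants in probands that would remain mono-allelic, and
#' variants predicted to create a canonical splice site. The remaining
#' variants are returned in input order.
#'
#' @param candidates data frame with a `variant` column and logical (or 0/1)
#'   flag columns `is_stop_gain`, `is_canonical`, `previously_characterized`,
#'   `is_artifact`, `remains_monoallelic`, `predicts_canonical_gain`; an
#'   optional `manual_include` column marks pre-SpliceAI additions (kept
#'   unless flagged).
#' @return the subset of `candidates` selected for assay, with an
#'   `excluded_counts` attribute tallying each exclusion class.
#' @export
select_for_minigene <- function(candidates) {
  missing <- setdiff(MINIGENE_EXCLUSION_FLAGS, names(candidates))
  if (length(missing))
    stop("candidate table lacks flag column(s): ", paste(missing, collapse = ", "))
  if (nrow(candidates) == 0) {
    out <- candidates
    attr(out, "excluded_counts") <- stats::setNames(
      integer(length(MINIGENE_EXCLUSION_FLAGS)), MINIGENE_EXCLUSION_FLAGS)
    return(out)
  }
  flags <- vapply(MINIGENE_EXCLUSION_FLAGS,
                  function(f) as.logical(candidates[[f]]),
                  logical(nrow(candidates)))
  flags <- matrix(flags, nrow = nrow(candidates),
                  dimnames = list(NULL, MINIGENE_EXCLUSION_FLAGS))
  excluded <- rowSums(flags, na.rm = TRUE) > 0
  out <- candidates[!excluded, , drop = FALSE]
  attr(out, "excluded_counts") <- colSums(flags, na.rm = TRUE)
  out
}
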