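# Assay-outcome-driven variant classification and per-proband case
# resolution: variants with a full stop-gain effect in all transcripts are
# pathogenic, in-frame deletions disrupting a predicted functional domain are
# likely pathogenic, and variants with remaining conventionally spliced
# transcript are VUS; two (likely) pathogenic alleles solve a case, one plus
# a causative VUS makes it possibly solved.

CLASSIFICATION_LEVELS <- c("benign", "likely_benign", "vus",
                           "likely_pathogenic", "pathogenic")
CASE_STATUS_LEVELS <- c("unsolved", "possibly_solved", "solved")
PTC_CLASSES <- c("ptc_frameshift", "ptc_in_inserted")

#' Normalise a classification label
#'
#' Maps printed ACMG labels ("Pathogenic", "Likely pathogenic", "VUS",
#' "Likely benign", "Benign") and their snake_case forms onto the internal
#' five-level scale; empty strings, `"-"` and NA map to NA (missing allele).
#'
#' @param x character vector of labels.
#' @return character vector over
#'   `c("benign","likely_benign","vus","likely_pathogenic","pathogenic")`.
#' @export
normalize_classification <- function(x) {
  key <- tolower(trimws(as.character(x)))
  key <- gsub("[ .]", "_", key)
  out <- ifelse(key %in% c("", "-", "na", "none"), NA_character_, key)
  map <- c(pathogenic = "pathogenic", likely_pathogenic = "likely_pathogenic",
           vus = "vus", variant_of_uncertain_significance = "vus",
           likely_benign = "likely_benign", benign = "benign")
  res <- unname(map[out])
  bad <- !is.na(out) & is.na(res)
  if (any(bad)) stop("unknown classification label(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  res
}

is_plp <- function(x) !is.na(x) & x %in% c("pathogenic", "likely_pathogenic")

#' Classify a variant from its minigene assay outcome
#'
#' Encodes the assay-based splice-variant rules: a variant whose every
#' transcript carries a premature-termination consequence (frameshift or
#' stop within inserted sequence) is pathogenic; a full in-frame deletion
#' effect that disrupts a predicted functional protein domain is likely
#' pathogenic (a full-effect outcome mixing PTC and in-frame consequences is
#' treated the same way); any outcome with remaining conventionally spliced
#' transcript is a VUS. An in-frame full effect without domain annotation is
#' a VUS with a warning. A variant with no splice effect at all is not
#' (re)classified by this rule and yields NA.
#'
#' @param outcome a [splice_outcome()], or NULL when `effect_classes` are
#'   given directly.
#' @param consequences optional list of `protein_consequence` objects for the
#'   outcome's events (computed with [consequence_for_outcome()] when
#'   omitted and a transcript is supplied).
#' @param domain_disrupted logical: does the in-frame deletion remove a
#'   predicted functional domain (from a domain table)?
#' @param effect_classes character vector of per-event effect classes, as an
#'   alternative to `outcome`+`consequences` (used with
#'   `conventional_present`).
#' @param conventional_present logical, used with `effect_classes`.
#' @return list with `label` (classification or NA) and `basis` (`"assay"`).
#' @export
classify_from_assay <- function(outcome = NULL, consequences = NULL,
                                domain_disrupted = FALSE,
                                effect_classes = NULL,
                                conventional_present = NULL) {
  if (is.null(effect_classes)) {
    stopifnot(inherits(outcome, "splice_outcome"))
    effect_classes <- vapply(consequences, function(x) x$effect_class, "")
    effect_classes <- effect_classes[effect_classes != "no_change"]
    conventional_present <- outcome$conventional_transcript_present
  }
  if (length(effect_classes) == 0)
    return(list(label = NA_character_, basis = "assay"))
  label <- if (conventional_present) {
    "vus"
  } else if (all(effect_classes %in% PTC_CLASSES)) {
    "pathogenic"
  } else if (domain_disrupted) {
    "likely_pathogenic"
  } else {
    warning("full in-frame effect without domain annotation; returning VUS")
    "vus"
  }
  list(label = label, basis = "assay")
}

#' Resolve a proband's case status from its allele classifications
#'
#' Two (likely) pathogenic alleles solve the case; exactly one (likely)
#' pathogenic allele with the other a VUS deemed potentially causative makes
#' it possibly solved; anything else (two VUS, any benign-class allele, a
#' non-causative VUS, fewer than two alleles) leaves it unsolved.
#'
#' @param class1,class2 classification labels (any form accepted by
#'   [normalize_classification()]); NA for a missing allele.
#' @param vus_causative1,vus_causative2 was the VUS allele deemed potentially
#'   causative? Defaults TRUE; only consulted for VUS alleles.
#' @return one of `"solved"`, `"possibly_solved"`, `"unsolved"`.
#' @export
resolve_case <- function(class1, class2, vus_causative1 = TRUE,
                         vus_causative2 = TRUE) {
  c1 <- normalize_classification(class1)
  c2 <- normalize_classification(class2)
  qual_vus <- function(cl, causative)
    !is.na(cl) && cl == "vus" && isTRUE(causative)
  if (is_plp(c1) && is_plp(c2)) return("solved")
  if ((is_plp(c1) && qual_vus(c2, vus_causative2)) ||
      (is_plp(c2) && qual_vus(c1, vus_causative1)))
    return("possibly_solved")
  "unsolved"
}

#' Enumerated reference table for case resolution
#'
#' Independent brute-force oracle over all ordered classification pairs
#' (including missing alleles): the status follows from literally counting
#' qualifying alleles, used to cross-check [resolve_case()].
#'
#' @return data frame with columns `class1`, `class2`, `status`.
#' @export
resolve_case_oracle_table <- function() {
  lv <- c(CLASSIFICATION_LEVELS, NA_character_)
  grid <- expand.grid(class1 = lv, class2 = lv, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$status <- apply(grid, 1L, function(r) {
    n_plp <- sum(r %in% c("pathogenic", "likely_pathogenic"))
    n_vus <- sum(r %in% "vus")
    if (n_plp == 2) "solved"
    else if (n_plp == 1 && n_vus == 1) "possibly_solved"
    else "unsolved"
  })
  grid
}
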